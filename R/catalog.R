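#' Symptom catalogue for the three DSM-IV-TR mood disorders
#'
#' Registry of the 34 binary input symptoms used to diagnose major depressive
#' episodes (`mde`), dysthymic disorder (`dys`) and manic episodes (`manic`).
#' Each symptom carries its disorder membership, its tier (major criteria vs
#' minor criteria) and the item it feeds: minor criteria are counted at the
#' item level, where an item is either a single symptom or the disjunction of
#' two related symptoms (e.g. "insomnia or sleeping too much").
#'
#' Six symptoms (the insomnia/hypersomnia, fatigue/low-energy and poor
#' concentration/indecisiveness pairs) are shared between the depressive and
#' dysthymic rules; the manic rule shares none.
#'
#' @return A data frame with columns `symptom_id`, `disorder`
#'   (`"mde"`, `"dys"`, `"manic"` or `"shared"` for the six mde/dys symptoms),
#'   `tier` (`"major"`/`"minor"`) and `item_group` (the item the symptom feeds).
#' @examples
#' nrow(symptom_catalog())  # 34
#' @export
symptom_catalog <- function() {
  entry <- function(id, disorder, tier, item) {
    data.frame(symptom_id = id, disorder = disorder, tier = tier,
               item_group = item, stringsAsFactors = FALSE)
  }
  rbind(
    entry("mde_ma1",   "mde",    "major", "mde_ma1"),
    entry("mde_ma2",   "mde",    "major", "mde_ma2"),
    entry("mde_mi3_1", "mde",    "minor", "mde_mi3"),
    entry("mde_mi3_2", "mde",    "minor", "mde_mi3"),
    entry("mde_mi4_1", "shared", "minor", "mde_mi4"),
    entry("mde_mi4_2", "shared", "minor", "mde_mi4"),
    entry("mde_mi5_1", "mde",    "minor", "mde_mi5"),
    entry("mde_mi5_2", "mde",    "minor", "mde_mi5"),
    entry("mde_mi6_1", "shared", "minor", "mde_mi6"),
    entry("mde_mi6_2", "shared", "minor", "mde_mi6"),
    entry("mde_mi7_1", "mde",    "minor", "mde_mi7"),
    entry("mde_mi7_2", "mde",    "minor", "mde_mi7"),
    entry("mde_mi8_1", "shared", "minor", "mde_mi8"),
    entry("mde_mi8_2", "shared", "minor", "mde_mi8"),
    entry("mde_mi9",   "mde",    "minor", "mde_mi9"),
    entry("dys_ma",    "dys",    "major", "dys_ma"),
    entry("dys_mi1_1", "dys",    "minor", "dys_mi1"),
    entry("dys_mi1_2", "dys",    "minor", "dys_mi1"),
    entry("dys_mi4",   "dys",    "minor", "dys_mi4"),
    entry("dys_mi6",   "dys",    "minor", "dys_mi6"),
    entry("man_ma1",   "manic",  "major", "man_ma1"),
    entry("man_ma2",   "manic",  "major", "man_ma2"),
    entry("man_ma3",   "manic",  "major", "man_ma3"),
    entry("man_mi1_1", "manic",  "minor", "man_mi1"),
    entry("man_mi1_2", "manic",  "minor", "man_mi1"),
    entry("man_mi2",   "manic",  "minor", "man_mi2"),
    entry("man_mi3_1", "manic",  "minor", "man_mi3"),
    entry("man_mi3_2", "manic",  "minor", "man_mi3"),
    entry("man_mi4_1", "manic",  "minor", "man_mi4"),
    entry("man_mi4_2", "manic",  "minor", "man_mi4"),
    entry("man_mi5",   "manic",  "minor", "man_mi5"),
    entry("man_mi6_1", "manic",  "minor", "man_mi6"),
    entry("man_mi6_2", "manic",  "minor", "man_mi6"),
    entry("man_mi7",   "manic",  "minor", "man_mi7")
  )
}

disorder_tokens <- c("mde", "dys", "manic")

check_disorder <- function(disorder) {
  if (length(disorder) != 1L || !disorder %in% disorder_tokens) {
    stop("unknown disorder '", paste(disorder, collapse = ","),
         "'; valid tokens: ", paste(disorder_tokens, collapse = ", "),
         call. = FALSE)
  }
  invisible(disorder)
}

#' Input symptoms of a disorder's diagnostic rule
#'
#' Returns the symptoms a disorder's own rule reads, in catalogue order.
#' These are the "own" predictors offered to its decision tree: 15 for major
#' depressive episodes, 11 for dysthymic disorder (six shared with mde) and
#' 14 for manic episodes.
#'
#' @param disorder One of `"mde"`, `"dys"`, `"manic"`.
#' @return Character vector of symptom identifiers.
#' @examples
#' catalog("mde")
#' @export
catalog <- function(disorder) {
  check_disorder(disorder)
  cat_df <- symptom_catalog()
  if (disorder == "mde") {
    cat_df$symptom_id[cat_df$disorder %in% c("mde", "shared")]
  } else if (disorder == "dys") {
    # Table-1 order for the dysthymia rule: major symptom first, then the
    # minor items dys_mi1, mde_mi4, mde_mi6, dys_mi4, mde_mi8, dys_mi6.
    c("dys_ma", "dys_mi1_1", "dys_mi1_2", "mde_mi4_1", "mde_mi4_2",
      "mde_mi6_1", "mde_mi6_2", "dys_mi4", "mde_mi8_1", "mde_mi8_2", "dys_mi6")
  } else {
    cat_df$symptom_id[cat_df$disorder == "manic"]
  }
}

#' Symptoms shared between two diagnostic rules
#'
#' @param d1,d2 Distinct disorder tokens.
#' @return Character vector of shared symptom identifiers in catalogue order
#'   (empty when the rules are disjoint, as for the manic rule).
#' @examples
#' shared_symptoms("mde", "dys")
#' @export
shared_symptoms <- function(d1, d2) {
  check_disorder(d1)
  check_disorder(d2)
  if (d1 == d2) stop("d1 and d2 must be distinct disorder tokens", call. = FALSE)
  shared <- intersect(catalog(d1), catalog(d2))
  ord <- symptom_catalog()$symptom_id
  shared[order(match(shared, ord))]
}

#' Latent-block membership of each symptom
#'
#' The simulation correlates symptoms within two independent blocks: the 20
#' depressive/dysthymic symptoms and the 14 manic symptoms.
#'
#' @return Named character vector mapping symptom_id to
#'   `"depressive"` or `"manic"`.
#' @export
symptom_blocks <- function() {
  cat_df <- symptom_catalog()
  blocks <- ifelse(cat_df$disorder == "manic", "manic", "depressive")
  names(blocks) <- cat_df$symptom_id
  blocks
}
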