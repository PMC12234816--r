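#' Count-threshold diagnostic rules
#'
#' Declarative encodings of the DSM-IV-TR rules the simulation applies.
#' Each rule has:
#' \describe{
#'   \item{major}{symptoms that must all be present (for manic episodes only
#'     the irritable-mood symptom `man_ma3` is structurally required; the
#'     elevated/expansive mood symptoms enter through `branch`).}
#'   \item{items}{named list of minor-criteria items; each item is the
#'     disjunction of its constituent symptoms (singleton items pass through).}
#'   \item{threshold}{minimum count of positive minor items.}
#'   \item{branch}{manic episodes only: when exactly one of `man_ma1`,
#'     `man_ma2` is present the minor-item threshold is `threshold_one` (3);
#'     when neither or both are present ("mood only irritable" and the
#'     complementary case) it is `threshold_other` (4).}
#' }
#'
#' @return Named list of rules, one per disorder.
#' @examples
#' diagnosis_rules()$dys$threshold  # 2
#' @export
diagnosis_rules <- function() {
  list(
    mde = list(
      disorder = "mde",
      major = c("mde_ma1", "mde_ma2"),
      items = list(
        mde_mi3 = c("mde_mi3_1", "mde_mi3_2"),
        mde_mi4 = c("mde_mi4_1", "mde_mi4_2"),
        mde_mi5 = c("mde_mi5_1", "mde_mi5_2"),
        mde_mi6 = c("mde_mi6_1", "mde_mi6_2"),
        mde_mi7 = c("mde_mi7_1", "mde_mi7_2"),
        mde_mi8 = c("mde_mi8_1", "mde_mi8_2"),
        mde_mi9 = "mde_mi9"
      ),
      threshold = 3L,
      branch = NULL
    ),
    dys = list(
      disorder = "dys",
      major = "dys_ma",
      items = list(
        dys_mi1 = c("dys_mi1_1", "dys_mi1_2"),
        mde_mi4 = c("mde_mi4_1", "mde_mi4_2"),
        mde_mi6 = c("mde_mi6_1", "mde_mi6_2"),
        dys_mi4 = "dys_mi4",
        mde_mi8 = c("mde_mi8_1", "mde_mi8_2"),
        dys_mi6 = "dys_mi6"
      ),
      threshold = 2L,
      branch = NULL
    ),
    manic = list(
      disorder = "manic",
      major = "man_ma3",
      items = list(
        man_mi1 = c("man_mi1_1", "man_mi1_2"),
        man_mi2 = "man_mi2",
        man_mi3 = c("man_mi3_1", "man_mi3_2"),
        man_mi4 = c("man_mi4_1", "man_mi4_2"),
        man_mi5 = "man_mi5",
        man_mi6 = c("man_mi6_1", "man_mi6_2"),
        man_mi7 = "man_mi7"
      ),
      threshold = NA_integer_,
      branch = list(
        symptoms = c("man_ma1", "man_ma2"),
        threshold_one = 3L,
        threshold_other = 4L
      )
    )
  )
}

#' Read diagnostic rules from their shipped declarative file
#'
#' The rules are also distributed as a versioned YAML document
#' (`inst/extdata/diagnosis_rules.yaml`) so that the encoded logic can be
#' inspected and cross-checked outside R.
#'
#' @param path Path to a rules YAML file; defaults to the copy installed with
#'   the package.
#' @return Rules in the same structure as [diagnosis_rules()].
#' @export
read_diagnosis_rules <- function(path = system.file("extdata", "diagnosis_rules.yaml",
                                                    package = "moodtrees")) {
  doc <- yaml::read_yaml(path)
  lapply(doc$disorders, function(r) {
    list(
      disorder = r$disorder,
      major = as.character(unlist(r$major)),
      items = lapply(r$items, function(x) as.character(unlist(x))),
      threshold = if (is.null(r$threshold)) NA_integer_ else as.integer(r$threshold),
      branch = if (is.null(r$branch)) NULL else list(
        symptoms = as.character(unlist(r$branch$symptoms)),
        threshold_one = as.integer(r$branch$threshold_one),
        threshold_other = as.integer(r$branch$threshold_other)
      )
    )
  })
}

# All item groups (majors pass through, minor items may be disjunctions),
# derived from the catalogue's item_group column.
item_registry <- function() {
  cat_df <- symptom_catalog()
  split(cat_df$symptom_id, cat_df$item_group)
}

#' Value of an intermediate item for one subject
#'
#' Minor-criteria items formed from two symptoms take the value of their
#' disjunction; singleton items (and major symptoms) pass their symptom value
#' through.
#'
#' @param item_group Item identifier, e.g. `"mde_mi4"`, `"dys_mi1"`,
#'   `"man_mi5"`.
#' @param subject Named vector (or single-row data) of 0/1 symptom values.
#' @return 0 or 1.
#' @examples
#' intermediate_value("mde_mi4", c(mde_mi4_1 = 1, mde_mi4_2 = 0))  # 1
#' @export
intermediate_value <- function(item_group, subject) {
  reg <- item_registry()
  if (!item_group %in% names(reg)) {
    stop("unknown item_group '", item_group, "'", call. = FALSE)
  }
  constituents <- reg[[item_group]]
  vals <- unlist(subject)[constituents]
  if (anyNA(vals)) {
    stop("missing symptom values for: ",
         paste(constituents[is.na(vals)], collapse = ", "), call. = FALSE)
  }
  as.integer(max(vals) > 0)
}

check_symptom_values <- function(x, needed) {
  missing_ids <- setdiff(needed, colnames(x))
  if (length(missing_ids)) {
    stop("missing symptom values for: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  vals <- x[, needed, drop = FALSE]
  if (!all(vals %in% c(0, 1))) {
    stop("symptom values must be 0 or 1", call. = FALSE)
  }
  invisible(x)
}

# Vectorized rule evaluation on a 0/1 matrix with symptom_id column names.
apply_rule <- function(rule, mat) {
  needed <- unique(c(rule$major, unlist(rule$items),
                     if (!is.null(rule$branch)) rule$branch$symptoms))
  check_symptom_values(mat, needed)
  major_ok <- rep(TRUE, nrow(mat))
  for (s in rule$major) major_ok <- major_ok & (mat[, s] == 1)
  item_vals <- vapply(rule$items, function(constituents) {
    if (length(constituents) == 1L) {
      mat[, constituents]
    } else {
      as.numeric(mat[, constituents[1]] | mat[, constituents[2]])
    }
  }, numeric(nrow(mat)))
  if (nrow(mat) == 1L) item_vals <- matrix(item_vals, nrow = 1)
  m <- rowSums(item_vals)
  if (is.null(rule$branch)) {
    as.integer(major_ok & m >= rule$threshold)
  } else {
    one <- (mat[, rule$branch$symptoms[1]] + mat[, rule$branch$symptoms[2]]) == 1
    as.integer(major_ok &
                 ((one & m >= rule$branch$threshold_one) |
                    (!one & m >= rule$branch$threshold_other)))
  }
}

#' Diagnose one subject
#'
#' Applies a disorder's count-threshold rule to a single subject's symptom
#' values.
#'
#' @param disorder One of `"mde"`, `"dys"`, `"manic"`.
#' @param subject Named vector of 0/1 symptom values covering the rule's
#'   symptoms.
#' @return 0 or 1.
#' @examples
#' s <- setNames(rep(0, 34), symptom_catalog()$symptom_id)
#' diagnose("mde", s)  # 0
#' @export
diagnose <- function(disorder, subject) {
  check_disorder(disorder)
  vals <- unlist(subject)
  mat <- matrix(vals, nrow = 1, dimnames = list(NULL, names(vals)))
  apply_rule(diagnosis_rules()[[disorder]], mat)
}

#' Diagnose every subject in a cohort
#'
#' @param disorder One of `"mde"`, `"dys"`, `"manic"`.
#' @param cohort A [simulate_cohort()] result, or any 0/1 matrix / data frame
#'   with symptom identifiers as column names.
#' @return Integer 0/1 vector of length `n`, with attribute `"prevalence"`
#'   (the diagnosed fraction).
#' @export
diagnose_cohort <- function(disorder, cohort) {
  check_disorder(disorder)
  mat <- if (inherits(cohort, "mood_cohort")) cohort$matrix else as.matrix(cohort)
  out <- apply_rule(diagnosis_rules()[[disorder]], mat)
  attr(out, "prevalence") <- mean(out)
  out
}
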