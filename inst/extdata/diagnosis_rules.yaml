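# Declarative DSM-IV-TR count-threshold rules for the three mood disorders.
# Items listed under `items` are disjunctions of their constituent symptoms
# (singletons pass through). `major` symptoms must all be present. The manic
# rule is branch-dependent: with exactly one of the branch symptoms present
# the minor-item threshold is threshold_one, otherwise threshold_other.
version: 1
disorders:
  mde:
    disorder: mde
    major: [mde_ma1, mde_ma2]
    items:
      mde_mi3: [mde_mi3_1, mde_mi3_2]
      mde_mi4: [mde_mi4_1, mde_mi4_2]
      mde_mi5: [mde_mi5_1, mde_mi5_2]
      mde_mi6: [mde_mi6_1, mde_mi6_2]
      mde_mi7: [mde_mi7_1, mde_mi7_2]
      mde_mi8: [mde_mi8_1, mde_mi8_2]
      mde_mi9: [mde_mi9]
    threshold: 3
  dys:
    disorder: dys
    major: [dys_ma]
    items:
      dys_mi1: [dys_mi1_1, dys_mi1_2]
      mde_mi4: [mde_mi4_1, mde_mi4_2]
      mde_mi6: [mde_mi6_1, mde_mi6_2]
      dys_mi4: [dys_mi4]
      mde_mi8: [mde_mi8_1, mde_mi8_2]
      dys_mi6: [dys_mi6]
    threshold: 2
  manic:
    disorder: manic
    major: [man_ma3]
    items:
      man_mi1: [man_mi1_1, man_mi1_2]
      man_mi2: [man_mi2]
      man_mi3: [man_mi3_1, man_mi3_2]
      man_mi4: [man_mi4_1, man_mi4_2]
      man_mi5: [man_mi5]
      man_mi6: [man_mi6_1, man_mi6_2]
      man_mi7: [man_mi7]
    branch:
      symptoms: [man_ma1, man_ma2]
      threshold_one: 3
      threshold_other: 4
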