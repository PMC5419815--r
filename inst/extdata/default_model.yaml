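# Default model configuration: 4 vulnerability + 4 exposure indicators.
#
# Cut-off values are PROVISIONAL, chosen from typical least-developed-country
# ranges of the underlying development and displacement statistics. They are
# configuration, not code: review and edit them before any real assessment.
#
# direction semantics:
#   higher_is_worse: value <  cutoff_lo -> low_medium
#                    value >= cutoff_lo and < cutoff_hi -> high
#                    value >= cutoff_hi -> extreme
#   lower_is_worse:  mirrored (cutoff_lo > cutoff_hi); a value exactly at a
#                    cut-off is always assigned the more severe level.
indicators:
  - name: gni_per_capita_ppp
    dimension: vulnerability
    direction: lower_is_worse
    cutoff_lo: 3000
    cutoff_hi: 1500
    units: international dollars (PPP) per person per year
  - name: adult_literacy
    dimension: vulnerability
    direction: lower_is_worse
    cutoff_lo: 70
    cutoff_hi: 45
    units: percent of adults (15+) literate
  - name: child_underweight
    dimension: vulnerability
    direction: higher_is_worse
    cutoff_lo: 20
    cutoff_hi: 30
    units: percent of children under 5 underweight
  # placeholder fourth vulnerability slot (editable)
  - name: life_expectancy
    dimension: vulnerability
    direction: lower_is_worse
    cutoff_lo: 60
    cutoff_hi: 52
    units: years at birth
  - name: uprooted_number
    dimension: exposure
    direction: higher_is_worse
    cutoff_lo: 200000
    cutoff_hi: 1000000
    units: refugees + internally displaced persons
  - name: uprooted_proportion
    dimension: exposure
    direction: higher_is_worse
    cutoff_lo: 5
    cutoff_hi: 15
    units: percent of total population uprooted
  - name: people_in_need_number
    dimension: exposure
    direction: higher_is_worse
    cutoff_lo: 1000000
    cutoff_hi: 4000000
    units: persons in need of humanitarian assistance
  # placeholder fourth exposure slot (editable)
  - name: people_in_need_proportion
    dimension: exposure
    direction: higher_is_worse
    cutoff_lo: 10
    cutoff_hi: 25
    units: percent of total population in need
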