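# Small hand-built fixtures used across tests.

tiny_resources <- function() {
  resource_table(
    item_id = c("glove", "monitor", "nurse"),
    name = c("examination gloves", "patient monitor", "nurse time"),
    category = c("ppe", "nonpharma_capital", "staffing"),
    stream = c("identification", "identification", "identification"),
    applicability = c("both", "both", "both"),
    qty_moderate = c(4, 0.01, 20),
    qty_severe = c(8, 0.02, 60),
    qty_critical = c(12, 0.05, 90),
    unit = c("pair", "device fraction", "minutes")
  )
}

tiny_pricebook <- function() {
  pricebook(
    item_id = c("glove", "monitor", "nurse"),
    price = c(230, 2300000, 10800000),
    currency = c("TZS", "TZS", "TZS"),
    cost_type = c("recurrent", "capital", "staff_time"),
    useful_life_years = c(NA, 5, NA),
    needs_uplift = c(TRUE, TRUE, FALSE),
    source = "fixture"
  )
}

# Independent annuity-factor oracle: explicit sum of discounted year weights.
af_oracle <- function(r, life) {
  if (r == 0) return(life)
  sum((1 + r)^-(seq_len(life)))
}
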