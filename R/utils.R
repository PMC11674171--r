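# Shared internal helpers.

# Round half away from zero (spreadsheet-style "half-up" for non-negative
# values). base::round() rounds half to even, which is not bit-reproducible
# against the documented gray conversion contract.
round_half_up <- function(x) floor(x + 0.5)

clamp8 <- function(x) pmin(pmax(x, 0), 255)

stop_hcg <- function(message, class, ...) {
  abort(message, class = c(class, "hcg_error"), ...)
}

# Linear-interpolation quantiles (type 7), the convention used for all
# IQR summaries in reports.
iqr_quantiles <- function(x) {
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE, na.rm = TRUE)
  list(q25 = q[[1]], median = q[[2]], q75 = q[[3]])
}
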