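# Golden-test tolerances, each tied to the rounding precision of the
# corresponding printed quantity.
TOL <- list(
  predicted_days = 0.05,  # predicted columns print 2 dp but their corner
                          # entries are not jointly consistent with one
                          # 6-term fit at 0.01 precision
  predicted_days_tight = 0.02,  # entries that do reproduce a single fit
  r2 = 0.002,             # R-squared family printed to 4 dp
  ss_rel = 0.02,          # sums of squares / F ratios: 2 percent relative
  lof_f = 0.03,           # lack-of-fit F printed to 4 significant digits
  adeq = 1.5,             # adequate precision, looser (depends on spread)
  rate = 0.02,            # optimum rates printed to 2-3 dp
  opt_days = 0.15,        # optimum predicted response, days
  exact = 1e-8            # oracle-equivalence checks
)
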