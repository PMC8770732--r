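# DEMO clock coefficients -- NOT published clock coefficients.
# These values are the algebraic inverse of this package's default synthetic
# generator (see matched_clock()); they exist so the pipeline can be run
# end-to-end out of the box. To evaluate a real pyrosequencing clock,
# replace intercepts and coefficients with the published ones for your assay.
models:
  - id: clock2_demo
    intercept: -48.57142857142857
    terms:
      - {site: ELOVL2_6, coef: 1.0}
      - {site: PDE4C_1, coef: 1.4285714285714286}
    valid_age_range: [0, 101]
  - id: clock4_demo
    intercept: 75.71428571428571
    terms:
      - {site: ELOVL2_6, coef: 0.5}
      - {site: ASPA_1, coef: -1.0}
      - {site: PDE4C_1, coef: 0.7142857142857143}
      - {site: EDARADD_1, coef: -0.8333333333333334}
    valid_age_range: [0, 101]
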