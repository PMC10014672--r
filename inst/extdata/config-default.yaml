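# Decision-model configuration for the TACE cost-utility pipeline.
#
# All costs are Euro (2020 price level; the label carries no inflation
# adjustment), utilities are per-year preference weights in [0, 1], times
# are years. Standard errors (se) feed the probabilistic sensitivity
# analysis only; the base case uses the point values.

# Cost scenario used for the base-case analysis: "median" or "mean".
# Follow-up cost data are heavily skewed, so both are informative.
scenario: median

# Willingness-to-pay threshold (Euro per QALY) for net-monetary-benefit
# decisions and the acceptability-curve marker.
wtp: 25000

# Annual discount rate applied to both costs and QALYs (0 = undiscounted).
discount_rate: 0.0

# Lifetime horizon: maximum number of 1-year cycles; the engine also stops
# once the surviving fraction falls below 1e-9.
horizon_cycles: 40

# Half-cycle correction (average of start- and end-of-cycle occupancy).
half_cycle: false

# Use one estimated transition matrix per cycle instead of the single
# time-homogeneous first-year matrix.
time_varying: false

# State utilities, shared across arms. PLACEHOLDER values in the absence of
# a published utility set for this model: stable disease under palliative
# chemoembolization, post-recurrence, and post-transplant. The se defaults
# to 10% of the mean (an assumption; utility uncertainty is rarely
# reported).
utilities:
  stable:     {mean: 0.72, se: 0.072}
  recurrence: {mean: 0.50, se: 0.050}
  transplant: {mean: 0.82, se: 0.082}

# Per-arm inputs. State costs give the median-scenario and mean-scenario
# per-cycle values plus the standard error of the mean (SD / sqrt(n),
# n = 101 patients per arm) used by the PSA's normal cost distributions.
arms:
  C-TACE:
    reference: true          # comparator arm for incremental results
    p_transplant: 0.139      # observed transplant proportion
    cost_procedure: {mean: 3500, se: 0}   # tariff-valued, treated as fixed
    cost_stable:     {median: 0,    mean: 2463,  se: 659.31}
    cost_recurrence: {median: 4415, mean: 12406, se: 1727.39}
  DEM-TACE:
    reference: false
    p_transplant: 0.228
    cost_procedure: {mean: 3500, se: 0}
    cost_stable:     {median: 0,    mean: 2158,  se: 504.19}
    cost_recurrence: {median: 4085, mean: 11972, se: 1706.99}

# Probabilistic sensitivity analysis: number of simulations and the
# Dirichlet effective sample size for transition-row uncertainty (defaults
# to the per-arm sample size).
psa:
  n_sims: 10000
  ess: 101
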