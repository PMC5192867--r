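# Shared fixtures built in code.

# evaluate an analytic function over a design's rows (physical units)
eval_on_design <- function(design, f) apply(design$rows, 1, f)

# deterministic contract model: y(t) = slope * a at every tick
ramp_model <- function(slope = 2, ticks_cols = "y") {
  sa_model("ramp", list(a = 0, b = 0),
           setup = function(params) {
             list(run = function(ticks)
               data.frame(tick = seq_len(ticks),
                          y = rep(slope * as.numeric(params$a), ticks)))
           })
}

# stochastic contract model: i.i.d. normal(mean, sd) output each tick
noise_model <- function(mean = 10, sd = 2) {
  sa_model("noise", list(mu = mean, sigma = sd),
           setup = function(params) {
             list(run = function(ticks)
               data.frame(tick = seq_len(ticks),
                          y = stats::rnorm(ticks, as.numeric(params$mu),
                                           as.numeric(params$sigma))))
           })
}

unit_table <- function(k) {
  do.call(factor_table,
          stats::setNames(rep(list(c(0, 1)), k), paste0("x", seq_len(k))))
}
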