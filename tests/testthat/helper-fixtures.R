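# shared fixtures, all built in code

# canonical curve used throughout: the unit-tested Blanchard parameter set
tpc_ref <- function() list(mu_max = 1.5, t_opt = 20, t_max = 30, beta = 2)

assay_temps <- function() c(0.5, 5, 10, 15, 20, 25, 33)

# random valid Blanchard parameter sets (caller controls the RNG stream)
random_tpc <- function(n) {
  t_opt <- runif(n, 5, 28)
  data.frame(mu_max = runif(n, 0.2, 3),
             t_opt = t_opt,
             t_max = t_opt + runif(n, 2, 15),
             beta = runif(n, 0.2, 6))
}
random_tpc_row <- function(df, i) as.list(df[i, ])

# doubling fluorescence series: exact rate 1 division/day
doubling_series <- function()
  fluorescence_series("dbl", 20, 1, 0:3, c(100, 200, 400, 800))

# small non-clocklike rooted tree
nonclock_tree <- function()
  ape::read.tree(text = "((A:0.12,B:0.07):0.05,C:0.25);")
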