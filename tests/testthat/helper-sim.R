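# Shared simulation fixtures, built once per test run and memoised so that
# several test files can reuse the expensive ones.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# small, fast experiment with all effects on (default parameters otherwise)
small_sim <- function() {
  cached("small", simulate_experiment(sim_config(seed = 7, n_genes = 60)))
}

small_cpg <- function() {
  cached("small_cpg", normalize_coverage(filter_coverage(small_sim()$methylation)))
}

small_expr <- function() {
  cached("small_expr", tmm_factors(filter_expressed(small_sim()$expression)))
}

# full-size experiment at the generator defaults (used by the acceptance
# structural / association checks)
default_sim <- function() {
  cached("default", simulate_experiment(sim_config(seed = 17)))
}

default_cpg <- function() {
  cached("default_cpg",
         normalize_coverage(filter_coverage(default_sim()$methylation)))
}

default_expr <- function() {
  cached("default_expr",
         tmm_factors(filter_expressed(default_sim()$expression)))
}

# the nine standard comparisons and a canonical two-group contrast
std_pools <- experiment_pools()
std_cmp <- standard_comparisons(std_pools)
grp_a <- std_cmp$group_a[[4]] # non-transgenic Day0
grp_b <- std_cmp$group_b[[4]] # non-transgenic Day28

# hand-built tiny CpG container: `frac` methylation everywhere
flat_cpg <- function(positions, pools, coverage = 10, frac = 0.5,
                     chrom = "chrS") {
  n <- length(positions)
  p <- nrow(pools)
  meth <- matrix(as.integer(round(coverage * frac)), n, p,
                 dimnames = list(NULL, pools$pool_id))
  unmeth <- matrix(as.integer(coverage - round(coverage * frac)), n, p,
                   dimnames = list(NULL, pools$pool_id))
  cpg_counts(tibble::tibble(chrom = chrom, pos = positions),
             meth, unmeth, pools)
}
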