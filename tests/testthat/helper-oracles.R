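# Independent oracle implementations and shared fixtures. The oracles are
# deliberately written as plain loops, separate from the package code
# paths they check.

oracle_is_missing <- function(x) {
  if (is.character(x)) !(toupper(x) %in% c("A", "C", "G", "T")) else is.na(x)
}

oracle_segregating_sites <- function(mat) {
  thr <- min(4L, nrow(mat))
  s <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[!oracle_is_missing(col)]
    if (length(col) >= thr && length(unique(col)) >= 2) s <- s + 1L
  }
  s
}

oracle_pi_total <- function(mat) {
  n <- nrow(mat)
  tot <- 0
  np <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !oracle_is_missing(mat[i, ]) & !oracle_is_missing(mat[j, ])
      tot <- tot + sum(mat[i, ok] != mat[j, ok])
      np <- np + 1L
    }
  }
  tot / np
}

# Tajima (1989) D written out independently
oracle_tajima_d <- function(mat) {
  n <- nrow(mat)
  S <- oracle_segregating_sites(mat)
  if (S == 0) return(NA_real_)
  pi <- oracle_pi_total(mat)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- (2 * (n * n + n + 3)) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  (pi - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1 * a1 + a2)) * S * (S - 1))
}

rand_binary_matrix <- function(n, s, miss = 0) {
  m <- matrix(rbinom(n * s, 1, runif(s)[rep(1:s, each = n)]), nrow = n)
  if (miss > 0) m[runif(length(m)) < miss] <- NA
  m
}

# three-population model with constant sizes and fixed split times;
# gen_time = 1 keeps event times in generations for oracle comparisons
const_model <- function(ne = 1e4, tdiv_ab = 5e7, tdiv_abc = 1e8,
                        extra_events = list(), extra_params = list()) {
  demographic_model(
    "const", "constant size",
    params = c(list(Ne_A = list(fixed = ne), Ne_B = list(fixed = ne),
                    Ne_C = list(fixed = ne),
                    tdiv_AB = list(fixed = tdiv_ab),
                    tdiv_ABC = list(fixed = tdiv_abc)),
               extra_params),
    events = c(list(evt_split("tdiv_AB", "A", "AB"),
                    evt_split("tdiv_AB", "B", "AB"),
                    evt_split("tdiv_ABC", "AB", "ABC"),
                    evt_split("tdiv_ABC", "C", "ABC")),
               extra_events))
}

GEN1 <- evo_constants(gen_time = 1)

# template for shared-divergence comparisons: constant sizes anchored at
# a declared reference so split times are identifiable in years
anchored_template <- function(ne_ref = 2e5) {
  demographic_model(
    "anchored", "Divergences (anchored scale)",
    params = list(Ne_A = list(fixed = ne_ref), Ne_B = list(fixed = ne_ref),
                  Ne_C = list(fixed = ne_ref),
                  tdiv_AB = list(lower = 1e4, upper = 1e7),
                  tdiv_ABC = list(lower = 1e4, upper = 1e7)),
    events = list(evt_split("tdiv_AB", "A", "AB"),
                  evt_split("tdiv_AB", "B", "AB"),
                  evt_split("tdiv_ABC", "AB", "ABC"),
                  evt_split("tdiv_ABC", "C", "ABC")))
}

# warm start for a migration model from a fit of the nested no-migration
# model: shared symbols copied, pulse fractions at their lower bound
warm_from_nested <- function(mig_model, nested_fit) {
  p <- midpoint_params(mig_model)
  shared <- intersect(names(p), names(nested_fit$params))
  p[shared] <- nested_fit$params[shared]
  bounds <- param_bounds(mig_model)
  psyms <- intersect(grep("^p2?_", names(p), value = TRUE), rownames(bounds))
  p[psyms] <- bounds[psyms, "lower"]
  p
}

# mean TMRCA and mean total branch length from msprime (independent
# coalescent simulator used as a test-only oracle); returns a list of
# per-scenario summaries
msprime_oracle <- function(n_reps = 3000L, seed = 7L) {
  script <- sprintf('
import json, msprime
def summarize(dem, samples, n_reps, seed):
    t, l = [], []
    for ts in msprime.sim_ancestry(samples=samples, demography=dem,
                                   ploidy=1, num_replicates=n_reps,
                                   random_seed=seed):
        tr = ts.first()
        t.append(tr.time(tr.root)); l.append(tr.total_branch_length)
    m = lambda v: sum(v)/len(v)
    sd = lambda v: (sum((x-m(v))**2 for x in v)/(len(v)-1))**0.5
    return dict(tmrca=m(t), tmrca_sd=sd(t), tlen=m(l), tlen_sd=sd(l))
out = {}
d = msprime.Demography()
d.add_population(name="A", initial_size=2e4)  # 2*Ne: ploidy-1 time scale
out["single"] = summarize(d, {"A": 10}, %d, %d)
d = msprime.Demography()
d.add_population(name="A", initial_size=4e4)
d.add_population(name="B", initial_size=4e4)
d.add_population(name="AB", initial_size=4e4)
d.add_population_split(time=5000, derived=["A","B"], ancestral="AB")
out["split"] = summarize(d, {"A": 8, "B": 8}, %d, %d)
d = msprime.Demography()
d.add_population(name="A", initial_size=2e5, growth_rate=1e-3)
d.add_population_parameters_change(time=4000, population="A",
                                   growth_rate=0, initial_size=2e3)
out["growth"] = summarize(d, {"A": 10}, %d, %d)
print(json.dumps(out))
', n_reps, seed, n_reps, seed + 1, n_reps, seed + 2)
  out <- system2("python", "-", stdout = TRUE, input = script)
  jsonlite::fromJSON(out[length(out)])
}
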