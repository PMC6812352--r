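# Shared fixtures, all built in code. Heavy objects are cached for the run.

.cache <- new.env(parent = emptyenv())

# 5x5 grid with cell centers on integer lon/lat coordinates:
# center of cell (r, c) is (c - 1, 5 - r).
unit_stack <- function(layers = NULL) {
  if (is.null(layers)) {
    layers <- list(a = matrix(seq_len(25), 5, 5))
  }
  predictor_stack(layers, origin = c(-0.5, 4.5), cell_size = 1)
}

# deterministic little stack for correlation work
corr_stack <- function() {
  a <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3)
  predictor_stack(
    list(a = a, b = 2 * a + 1, c = matrix(c(5, 1, 4, 2, 8, 3, 7, 6, 9), 3, 3)),
    origin = c(0, 3), cell_size = 1
  )
}

# standard virtual-species fixture: 60x60, 3 informative layers, 300 presences
std_fixture <- function() {
  if (is.null(.cache$fix)) {
    st <- generate_stack(
      n_layers = 3, n_rows = 60, n_cols = 60, smoothing = 3,
      origin = c(100, 45), cell_size = 0.5, seed = 101
    )
    vs <- make_virtual_species(st, c(-1, 3, -2, 1.5), 300, seed = 102)
    .cache$fix <- list(stack = st, species = vs$species, occ = vs$occurrences)
  }
  .cache$fix
}

# full pipeline run (both algorithms) on the standard fixture
std_run <- function() {
  if (is.null(.cache$run)) {
    fix <- std_fixture()
    .cache$run <- suppressWarnings(suppressMessages(
      run_pipeline(fix$stack, fix$occ, sdm_config(seed = 7))
    ))
  }
  .cache$run
}

# ready-made block machinery on the standard fixture
std_datasets <- function(n_replicates = 3) {
  key <- paste0("ds", n_replicates)
  if (is.null(.cache[[key]])) {
    fix <- std_fixture()
    part <- partition_blocks(fix$occ)
    plan <- enumerate_folds(part)
    mask <- geographic_candidates(fix$stack, fix$occ, 2)
    .cache[[key]] <- suppressWarnings(suppressMessages(
      build_datasets(fix$occ, part, plan, mask, fix$stack,
        n_pa1 = 20000, n_replicates = n_replicates, seed = 31
      )
    ))
  }
  .cache[[key]]
}

# random evaluation sample with both classes present
random_sample <- function(n) {
  o <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
  p <- round(runif(n), 2) # rounding forces ties to occur
  list(p = p, o = o)
}

# independent ROC AUC oracle: trapezoid over the full threshold sweep
roc_auc_sweep <- function(p, o) {
  ts <- sort(unique(p), decreasing = TRUE)
  sens <- vapply(ts, function(t) mean(p[o == 1] >= t), numeric(1))
  fpr <- vapply(ts, function(t) mean(p[o == 0] >= t), numeric(1))
  x <- c(0, fpr, 1)
  y <- c(0, sens, 1)
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# test-side confusion-based objective, computed from scratch
objective_at <- function(method, t, p, o) {
  tp <- sum(p >= t & o == 1)
  fp <- sum(p >= t & o == 0)
  fn <- sum(o == 1) - tp
  tn <- sum(o == 0) - fp
  n <- length(p)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  switch(method,
    max_oa = (tp + tn) / n,
    max_tss = sens + spec - 1,
    max_kappa = {
      po <- (tp + tn) / n
      pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
      if (abs(1 - pe) < 1e-14) -Inf else (po - pe) / (1 - pe)
    },
    min_rocdist = -sqrt((1 - sens)^2 + (1 - spec)^2),
    sens_eq_spec = -abs(sens - spec),
    predprev_obs = -abs(mean(p >= t) - mean(o))
  )
}
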