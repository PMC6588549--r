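#' Sample decorrelated observations from trajectories
#'
#' Takes every `stride`-th sampled frame of each trajectory (skipping the
#' first frame, which lacks a predecessor for the velocity features) together
#' with its immediately preceding frame, and pools them across replicas.  The
#' stride should be at least the measured autocorrelation time of the chain
#' radius of gyration expressed in sampling intervals; [rg_lag1_autocorr()]
#' reports the lag-1 autocorrelation actually achieved.
#'
#' @param trajectories a list of [vwf_trajectory()] objects.
#' @param stride frame stride (>= 1).
#' @return An object of class `a2_observations`: arrays `pos_t`, `pos_prev`
#'   (`nobs x N x 3`, nm), matrix `tensions` (`nobs x N/2`, pN), data frame
#'   `provenance` (replica, frame, time) and the shared `params`.
#' @export
sample_observations <- function(trajectories, stride = 1L) {
  if (inherits(trajectories, "vwf_trajectory"))
    trajectories <- list(trajectories)
  stride <- as.integer(stride)
  if (stride < 1) stop("stride must be >= 1")
  params <- trajectories[[1]]$params
  n <- params$n_beads

  pieces <- lapply(trajectories, function(tr) {
    nf <- length(tr$times)
    if (nf <= stride)
      stop("stride ", stride, " leaves no observations in replica ",
           tr$replica, " (", nf, " frames)")
    idx <- seq.int(1L + stride, nf, by = stride)
    list(pos_t = tr$positions[idx, , , drop = FALSE],
         pos_prev = tr$positions[idx - 1L, , , drop = FALSE],
         tensions = tr$tensions[idx, , drop = FALSE],
         prov = data.frame(replica = tr$replica, frame = idx,
                           time = tr$times[idx]))
  })

  nobs <- sum(vapply(pieces, function(p) nrow(p$prov), integer(1)))
  pos_t <- array(0, c(nobs, n, 3))
  pos_prev <- array(0, c(nobs, n, 3))
  tensions <- matrix(0, nobs, n / 2)
  at <- 1L
  for (p in pieces) {
    k <- nrow(p$prov)
    pos_t[at:(at + k - 1), , ] <- p$pos_t
    pos_prev[at:(at + k - 1), , ] <- p$pos_prev
    tensions[at:(at + k - 1), ] <- p$tensions
    at <- at + k
  }
  structure(list(pos_t = pos_t, pos_prev = pos_prev, tensions = tensions,
                 provenance = do.call(rbind, lapply(pieces, `[[`, "prov")),
                 params = params, stride = stride),
            class = "a2_observations")
}

#' @export
print.a2_observations <- function(x, ...) {
  cat(sprintf("%d observations (%d beads) from %d replica(s), stride %d\n",
              nrow(x$provenance), dim(x$pos_t)[2],
              length(unique(x$provenance$replica)), x$stride))
  invisible(x)
}

# subset an observation pool by row index
subset_observations <- function(obs, idx) {
  structure(list(pos_t = obs$pos_t[idx, , , drop = FALSE],
                 pos_prev = obs$pos_prev[idx, , , drop = FALSE],
                 tensions = obs$tensions[idx, , drop = FALSE],
                 provenance = obs$provenance[idx, , drop = FALSE],
                 params = obs$params, stride = obs$stride),
            class = "a2_observations")
}

#' Lag-1 autocorrelation of the chain radius of gyration
#'
#' Diagnostic for the decorrelation stride: computed within each replica
#' across consecutive observations, then averaged over replicas weighted by
#' observation count.
#'
#' @param obs an [sample_observations()] result.
#' @return Scalar lag-1 autocorrelation.
#' @export
rg_lag1_autocorr <- function(obs) {
  nobs <- dim(obs$pos_t)[1]
  msd <- numeric(nobs)
  for (ax in 1:3) {
    m <- matrix(obs$pos_t[, , ax], nobs)
    msd <- msd + rowMeans((m - rowMeans(m))^2)
  }
  rg <- sqrt(msd)
  reps <- split(seq_along(rg), obs$provenance$replica)
  acs <- vapply(reps, function(i) {
    if (length(i) < 3) return(NA_real_)
    stats::cor(rg[i][-length(i)], rg[i][-1])
  }, numeric(1))
  w <- vapply(reps, length, integer(1))
  sum(acs * w, na.rm = TRUE) / sum(w[!is.na(acs)])
}

#' Balance an observation pool by chain-level A2 state
#'
#' Selects `n_total / 2` observations whose chains carry no unfolded A2
#' domain and `n_total / 2` with at least one unfolded domain, sampled
#' without replacement under a fixed seed.
#'
#' @param obs an [sample_observations()] result.
#' @param n_total even total number of observations to keep.
#' @param seed integer seed.
#' @param config a [label_config()].
#' @return A balanced `a2_observations` object.
#' @export
balance_by_chain_state <- function(obs, n_total, seed,
                                   config = label_config()) {
  if (n_total %% 2 != 0) stop("n_total must be even")
  chain <- as.integer(rowSums(obs$tensions > config$unfold_threshold) > 0)
  per <- n_total / 2
  pool0 <- which(chain == 0L)
  pool1 <- which(chain == 1L)
  if (length(pool0) < per)
    stop("insufficient folded-chain observations: have ", length(pool0),
         ", need ", per)
  if (length(pool1) < per)
    stop("insufficient unfolded-chain observations: have ", length(pool1),
         ", need ", per)
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  idx <- sort(c(sample(pool0, per), sample(pool1, per)))
  subset_observations(obs, idx)
}

#' Assemble a feature/response dataset at one resolution
#'
#' Extracts the full feature matrix (raw bead positions plus per-segment
#' conformational features) and the binary responses for every observation.
#'
#' @param obs an [sample_observations()] result (typically balanced).
#' @param resolution 1, 5 or 10 segments.
#' @param config a [label_config()].
#' @return An object of class `a2_dataset` holding `features` (numeric
#'   matrix), `responses` (0/1 matrix, columns `y_s*` and `y_chain`),
#'   `resolution`, `provenance`, `params` and the reported `index_map`.
#' @export
build_dataset <- function(obs, resolution, config = label_config()) {
  part <- partition_chain(obs$params$n_beads, resolution)
  features <- featurize_positions(obs$pos_t, obs$pos_prev, obs$params,
                                  resolution)
  responses <- label_tensions(obs$tensions, part, config)
  structure(list(features = features, responses = responses,
                 resolution = as.integer(resolution),
                 provenance = obs$provenance, params = obs$params,
                 label_config = config,
                 index_map = feature_index_map(resolution),
                 split = NULL, seed = NULL),
            class = "a2_dataset")
}

#' Stratified train/test split
#'
#' Splits a dataset into training and test rows, stratified by the
#' chain-level response so both splits preserve the 50/50 class balance.
#'
#' @param dataset an [build_dataset()] result.
#' @param train_frac fraction of rows assigned to training (default 0.7).
#' @param seed integer seed.
#' @return The dataset with a `split` factor (`"train"`/`"test"`) filled in.
#' @export
split_dataset <- function(dataset, train_frac = 0.7, seed = 1L) {
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be in (0, 1)")
  y <- dataset$responses[, "y_chain"]
  n <- length(y)
  split <- rep("test", n)
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  for (cls in unique(y)) {
    rows <- which(y == cls)
    k <- round(train_frac * length(rows))
    split[sample(rows, k)] <- "train"
  }
  dataset$split <- factor(split, levels = c("train", "test"))
  dataset$seed <- as.integer(seed)
  dataset
}

#' @export
print.a2_dataset <- function(x, ...) {
  cat(sprintf("A2 dataset: %d observations x %d inputs, %d-segment resolution\n",
              nrow(x$features), ncol(x$features), x$resolution))
  y <- x$responses[, "y_chain"]
  cat(sprintf("  chain-level classes: %d folded / %d unfolded\n",
              sum(y == 0), sum(y == 1)))
  if (!is.null(x$split))
    cat(sprintf("  split: %d train / %d test\n",
                sum(x$split == "train"), sum(x$split == "test")))
  invisible(x)
}

# --- seeded sampling that does not disturb the caller's RNG -----------------
local_rng <- function(seed) {
  prev <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed %% 2147483647))
  prev
}

restore_rng <- function(prev) {
  if (is.null(prev)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", prev, envir = globalenv())
}
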