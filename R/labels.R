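#' Labelling configuration for A2 domain state
#'
#' An A2 domain is labelled unfolded when its FENE spring tension exceeds the
#' unfolding threshold, 11 pN by default (the centre of the 7-15 pN range
#' observed in single-molecule pulling experiments).  The comparison is
#' strict: a tension exactly at the threshold is labelled folded.
#'
#' @param unfold_threshold unfolding force threshold, pN (> 0).
#' @return An object of class `a2_label_config`.
#' @export
label_config <- function(unfold_threshold = 11) {
  if (unfold_threshold <= 0) stop("unfold_threshold must be > 0")
  structure(list(unfold_threshold = unfold_threshold),
            class = "a2_label_config")
}

#' Instantaneous A2 domain state from spring tension
#'
#' @param tension FENE spring tension(s), pN; must be >= 0.
#' @param config a [label_config()].
#' @return Integer 0 (folded) or 1 (unfolded), vectorised over `tension`.
#' @examples
#' cfg <- label_config()
#' a2_state(c(10.9, 11, 11.1), cfg)  # 0 0 1
#' @export
a2_state <- function(tension, config = label_config()) {
  if (any(tension < 0)) stop("tension must be >= 0")
  as.integer(tension > config$unfold_threshold)
}

#' Per-partition binary responses from spring states
#'
#' Spring `i` (connecting beads `2i - 1` and `2i`) belongs to the partition
#' containing those beads; a partition's response is 1 if any of its springs
#' is unfolded, and the chain-level response is the OR over all springs.
#'
#' @param spring_states integer vector of 0/1 spring states (length `N/2`).
#' @param partitioning a [partition_chain()] object.
#' @return A list with `segments` (0/1 vector of length `n_segments`) and
#'   `chain` (scalar 0/1).
#' @export
partition_response <- function(spring_states, partitioning) {
  n <- partitioning$n_beads
  if (length(spring_states) != n / 2)
    stop("expected ", n / 2, " spring states")
  if (n %% (2 * partitioning$n_segments) != 0)
    stop("partition boundaries split a monomer; n_beads must be divisible ",
         "by 2 * n_segments")
  if (!all(spring_states %in% c(0L, 1L))) stop("states must be 0 or 1")
  spring_seg <- ceiling(2 * seq_len(n / 2) / (n / partitioning$n_segments))
  segs <- vapply(seq_len(partitioning$n_segments),
                 function(s) as.integer(any(spring_states[spring_seg == s] == 1L)),
                 integer(1))
  list(segments = segs, chain = as.integer(any(segs == 1L)))
}

# Batched labelling: tensions is nobs x (N/2); returns nobs x (n_segments + 1)
# 0/1 matrix with columns y_s1..y_sn, y_chain.
label_tensions <- function(tensions, partitioning, config = label_config()) {
  n <- partitioning$n_beads
  nseg <- partitioning$n_segments
  states <- tensions > config$unfold_threshold
  spring_seg <- ceiling(2 * seq_len(n / 2) / (n / nseg))
  out <- matrix(0L, nrow(tensions), nseg + 1)
  for (s in seq_len(nseg))
    out[, s] <- as.integer(rowSums(states[, spring_seg == s, drop = FALSE]) > 0)
  out[, nseg + 1] <- as.integer(rowSums(states) > 0)
  colnames(out) <- c(paste0("y_s", seq_len(nseg)), "y_chain")
  out
}
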