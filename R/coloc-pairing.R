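#' Percentage of postsynapses colocalizing with tau
#'
#' Per-mouse statistic behind the tau-spread analysis: the number of
#' tau-colocalized postsynapses over the total postsynapses, pooled by sums
#' across crops (never the mean of crop percentages). Zero postsynapses
#' gives a missing value.
#'
#' @param records Colocalization records from [classify_overlap()] for all
#'   of a mouse's crops, row-bound.
#' @return Percentage in `[0, 100]`, or `NA_real_`.
#' @export
percent_post_tau <- function(records) {
  percent_positive(records)
}

#' Detect putative synaptic pairs by centroid proximity
#'
#' Candidate pairs are every (presynapse, postsynapse) combination whose 3D
#' Euclidean centroid distance — in physical micrometres, so the
#' anisotropic section axis is handled naturally — is at most
#' `max_pair_dist_um` (inclusive). Matching is one-to-one and greedy by
#' ascending distance, ties broken by `(pre id, post id)`, so each punctum
#' joins at most one pair and the result is deterministic. Set
#' `one_to_one = FALSE` to return all candidate pairs for sensitivity
#' analysis.
#'
#' @param pre A `puncta` tibble of presynapses (typically the GFP-positive
#'   subset).
#' @param post A `puncta` tibble of postsynapses, same coordinate frame.
#' @param max_pair_dist_um Inclusive pairing radius (default 0.5).
#' @param one_to_one Enforce one-to-one greedy matching (default `TRUE`).
#' @return Tibble `pre_id`, `post_id`, `distance_um`, ordered by ascending
#'   distance then ids.
#' @export
find_pairs <- function(pre, post, max_pair_dist_um = 0.5, one_to_one = TRUE) {
  empty <- tibble::tibble(pre_id = integer(0), post_id = integer(0),
                          distance_um = numeric(0))
  if (nrow(pre) == 0 || nrow(post) == 0) return(empty)
  dx <- outer(pre$centroid_x_um, post$centroid_x_um, "-")
  dy <- outer(pre$centroid_y_um, post$centroid_y_um, "-")
  dz <- outer(pre$centroid_z_um, post$centroid_z_um, "-")
  dist <- sqrt(dx^2 + dy^2 + dz^2)
  hit <- which(dist <= max_pair_dist_um, arr.ind = TRUE)
  if (nrow(hit) == 0) return(empty)
  cand <- tibble::tibble(pre_id = pre$id[hit[, 1]],
                         post_id = post$id[hit[, 2]],
                         distance_um = dist[hit])
  cand <- cand[order(cand$distance_um, cand$pre_id, cand$post_id), ]
  if (!one_to_one) return(cand)
  used_pre <- logical(max(cand$pre_id))
  used_post <- logical(max(cand$post_id))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    a <- cand$pre_id[i]; b <- cand$post_id[i]
    if (!used_pre[a] && !used_post[b]) {
      keep[i] <- TRUE
      used_pre[a] <- TRUE
      used_post[b] <- TRUE
    }
  }
  cand[keep, ]
}

#' Percentage of synaptic pairs in which both compartments are tau-positive
#'
#' A pair counts as tau-positive only when BOTH its presynaptic and
#' postsynaptic members colocalize with tau (each side classified with the
#' same overlap rule against the tau mask). Zero pairs gives a missing
#' value.
#'
#' @param pairs Tibble from [find_pairs()].
#' @param pre_records,post_records Records from [classify_overlap()] run on
#'   the pre and post collections against the tau mask; `id` columns must
#'   match the ids used in `pairs`.
#' @return Percentage in `[0, 100]`, or `NA_real_`.
#' @export
percent_pairs_tau <- function(pairs, pre_records, post_records) {
  if (nrow(pairs) == 0) return(NA_real_)
  pre_pos <- pre_records$positive[match(pairs$pre_id, pre_records$id)]
  post_pos <- post_records$positive[match(pairs$post_id, post_records$id)]
  if (anyNA(pre_pos) || anyNA(post_pos)) {
    stop("pair members missing from the colocalization records", call. = FALSE)
  }
  100 * sum(pre_pos & post_pos) / nrow(pairs)
}
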