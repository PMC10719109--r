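#' Vector copy number from coverage
#'
#' Normalizes mean coverage over the integrated-vector contig by half the
#' mean autosomal coverage (one vector copy is hemizygous against a diploid
#' genome) and subtracts the mismapping background estimated from
#' pre-transduction colonies.
#'
#' @param vector_cov mean coverage across the vector sequence.
#' @param autosomal_cov mean autosomal coverage (> 0).
#' @param background background VCN from pre-transduction colonies
#'   (default 0.3).
#' @return list with `raw` (background-subtracted continuous VCN) and
#'   `rounded` (nearest non-negative integer).
#' @export
vcn <- function(vector_cov, autosomal_cov, background = 0.3) {
  assert_that(all(autosomal_cov > 0), "autosomal coverage must be positive")
  raw <- vector_cov / (0.5 * autosomal_cov) - background
  list(raw = raw, rounded = pmax(0L, as.integer(round(raw))))
}

#' Background VCN from pre-transduction colonies
#'
#' Mean un-subtracted VCN across pre-transduction colonies, capturing reads
#' that mismap to the vector contig in colonies that cannot carry it.
#'
#' @param vector_cov,autosomal_cov per-colony coverages for >= 5
#'   pre-transduction colonies.
#' @return the background VCN.
#' @export
estimate_background <- function(vector_cov, autosomal_cov) {
  assert_that(length(vector_cov) >= 5,
              "need at least 5 pre-transduction colonies")
  mean(vector_cov / (0.5 * autosomal_cov))
}

# Exact 1-D k-medians by dynamic programming on sorted positions.
# cost(i, j) = sum |x - median(x[i..j])| via prefix sums.
kmedians_1d <- function(x, k) {
  x <- sort(x)
  n <- length(x)
  k <- min(k, n)
  S <- c(0, cumsum(x))
  cost <- function(i, j) {
    m <- (i + j) %/% 2
    xm <- x[m]
    right <- (S[j + 1] - S[m]) - (j - m + 1) * xm
    left <- (m - i + 1) * xm - (S[m + 1] - S[i])
    right + left
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in 1:n) { D[1, j] <- cost(1, j); B[1, j] <- 1L }
  if (k > 1) for (c in 2:k) for (j in c:n) {
    for (i in c:j) {
      v <- D[c - 1, i - 1] + cost(i, j)
      if (v < D[c, j]) { D[c, j] <- v; B[c, j] <- i }
    }
  }
  # backtrack
  bounds <- integer(k + 1); bounds[k + 1] <- n
  j <- n
  for (c in k:1) { bounds[c] <- B[c, j]; j <- B[c, j] - 1L }
  starts <- bounds[1:k]; ends <- c(bounds[2:k] - 1L, n)[1:k]
  if (k == 1) ends <- n
  clusters <- lapply(seq_len(k), function(c) x[starts[c]:ends[c]])
  list(clusters = clusters, cost = D[k, n],
       centers = vapply(clusters, median, numeric(1)),
       sizes = lengths(clusters))
}

# Laplace-model BIC for a k-medians partition of 1-D positions.
kmedians_bic <- function(part, n) {
  ll <- 0
  for (cl in part$clusters) {
    b <- max(mean(abs(cl - median(cl))), 0.5)
    ll <- ll + sum(-abs(cl - median(cl)) / b - log(2 * b))
  }
  -2 * ll + 2 * length(part$clusters) * log(n)
}

#' Call vector integration sites from anchored read positions
#'
#' Reads whose mates map into the vector contig anchor the integration site.
#' Per chromosome, positions (after blacklist filtering of recurrent
#' mismapping sites) are clustered by exact 1-D k-medians dynamic
#' programming for k in 1..3, with k selected by BIC under a per-cluster
#' Laplace dispersion model. Clusters whose central positions lie within 1 kb
#' are merged (support summed, centre re-computed as the median), and merged
#' clusters with at least `min_support` (4) assigned reads are emitted as
#' VIS calls.
#'
#' @param reads data frame with columns `chrom` and `pos` (1-based) for one
#'   colony.
#' @param blacklist optional data frame (`chrom`, `pos`) of recurrent
#'   mismapping positions; reads within `blacklist_window` of one are
#'   dropped.
#' @param min_support minimum reads per called VIS.
#' @param merge_distance merge clusters closer than this (bp).
#' @param max_k maximum clusters per chromosome.
#' @param blacklist_window half-width of the blacklist exclusion (bp).
#' @return data frame of VIS calls: `chrom`, `pos` (central), `support`.
#' @export
call_vis <- function(reads, blacklist = NULL, min_support = 4,
                     merge_distance = 1000, max_k = 3,
                     blacklist_window = 500) {
  empty <- data.frame(chrom = character(0), pos = numeric(0),
                      support = integer(0))
  if (NROW(reads) == 0) return(empty)
  if (!is.null(blacklist) && NROW(blacklist) > 0) {
    drop <- rep(FALSE, nrow(reads))
    for (i in seq_len(nrow(blacklist))) {
      drop <- drop | (reads$chrom == blacklist$chrom[i] &
                        abs(reads$pos - blacklist$pos[i]) <= blacklist_window)
    }
    reads <- reads[!drop, , drop = FALSE]
  }
  if (NROW(reads) == 0) return(empty)
  out <- list()
  for (ch in unique(reads$chrom)) {
    x <- sort(reads$pos[reads$chrom == ch])
    ks <- seq_len(min(max_k, length(x)))
    parts <- lapply(ks, function(k) kmedians_1d(x, k))
    bics <- vapply(parts, kmedians_bic, numeric(1), n = length(x))
    best <- parts[[which.min(bics)]]
    centers <- best$centers; sizes <- best$sizes
    # merge close clusters (centres < merge_distance apart)
    repeat {
      if (length(centers) < 2) break
      o <- order(centers); centers <- centers[o]; sizes <- sizes[o]
      gaps <- diff(centers)
      hit <- which(gaps < merge_distance)
      if (length(hit) == 0) break
      i <- hit[1]
      merged_center <- median(rep(centers[c(i, i + 1)], sizes[c(i, i + 1)]))
      centers <- c(centers[seq_len(i - 1)], merged_center,
                   centers[-seq_len(i + 1)])
      sizes <- c(sizes[seq_len(i - 1)], sizes[i] + sizes[i + 1],
                 sizes[-seq_len(i + 1)])
    }
    keep <- sizes >= min_support
    if (any(keep)) {
      out[[length(out) + 1]] <- data.frame(chrom = ch, pos = centers[keep],
                                           support = as.integer(sizes[keep]))
    }
  }
  if (length(out)) do.call(rbind, out) else empty
}

#' Build a recurrent-mismapping blacklist
#'
#' Positions of vector-anchored reads recurring in pre-transduction colonies
#' of more than `max_patients` distinct patients cannot be genuine
#' integrations and are blacklisted.
#'
#' @param reads data frame with `patient`, `chrom`, `pos` from
#'   pre-transduction colonies.
#' @param max_patients recurrence threshold (default 2).
#' @param window positions within this distance count as the same site.
#' @return data frame (`chrom`, `pos`) of blacklisted sites.
#' @export
vis_blacklist <- function(reads, max_patients = 2, window = 500) {
  if (NROW(reads) == 0) return(data.frame(chrom = character(0), pos = numeric(0)))
  out <- list()
  for (ch in unique(reads$chrom)) {
    sub <- reads[reads$chrom == ch, ]
    sub <- sub[order(sub$pos), ]
    grp <- cumsum(c(1, diff(sub$pos) > window))
    for (g in unique(grp)) {
      s <- sub[grp == g, ]
      if (length(unique(s$patient)) > max_patients) {
        out[[length(out) + 1]] <- data.frame(chrom = ch, pos = median(s$pos))
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), pos = numeric(0))
}

#' Classify a colony as gene-modified
#'
#' A colony is gene-modified when its rounded VCN is at least 1 or it has at
#' least one VIS call. Discordant evidence (VCN >= 1 without a VIS, or a VIS
#' with VCN 0) is flagged for review.
#'
#' @param vcn_rounded rounded vector copy number.
#' @param n_vis number of VIS calls.
#' @return list with `modified` and `discordant` logicals.
#' @export
classify_modified <- function(vcn_rounded, n_vis) {
  modified <- vcn_rounded >= 1 | n_vis >= 1
  discordant <- (vcn_rounded >= 1 & n_vis == 0) | (vcn_rounded == 0 & n_vis >= 1)
  list(modified = modified, discordant = discordant)
}
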