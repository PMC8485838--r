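#' @include diversity.R
NULL

#' Tamura-Nei (1993) pairwise distances
#'
#' TN93 corrects separately for the two transition classes (A<->G, C<->T) and
#' transversions, using base frequencies estimated from the whole matrix. For
#' any pair where a logarithm argument is non-positive (saturation), the
#' distance falls back to the raw p-distance with a warning.
#'
#' @param a A gap-free [HaploAlignment] or character vector of equal-length
#'   sequences over A/C/G/T.
#' @return A symmetric numeric matrix of per-site distances.
#' @export
tamuraNeiDistance <- function(a) {
  seqs <- if (is(a, "HaploAlignment")) as.character(a@seqs) else a
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("S", seq_along(seqs))
  # distances depend only on the sequence, so compute on unique sequences
  # and expand back to the sample level
  uniq <- unique(unname(seqs))
  idx <- match(unname(seqs), uniq)
  m <- do.call(rbind, strsplit(uniq, "", fixed = TRUE))
  L <- ncol(m)
  f <- table(factor(m[idx, , drop = FALSE], levels = c("A", "C", "G", "T"))) /
    (n * L)
  gA <- f[["A"]]; gC <- f[["C"]]; gG <- f[["G"]]; gT <- f[["T"]]
  gR <- gA + gG; gY <- gC + gT
  k1 <- 2 * gA * gG / gR
  k2 <- 2 * gC * gT / gY
  k3 <- 2 * (gR * gY - gA * gG * gY / gR - gC * gT * gR / gY)
  k <- nrow(m)
  du <- matrix(0, k, k)
  fell_back <- FALSE
  if (k >= 2) {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      x <- m[i, ]; y <- m[j, ]
      diff <- x != y
      P1 <- sum(diff & ((x == "A" & y == "G") | (x == "G" & y == "A"))) / L
      P2 <- sum(diff & ((x == "C" & y == "T") | (x == "T" & y == "C"))) / L
      Q <- sum(diff) / L - P1 - P2
      w1 <- 1 - P1 / k1 - Q / (2 * gR)
      w2 <- 1 - P2 / k2 - Q / (2 * gY)
      w3 <- 1 - Q / (2 * gR * gY)
      if (w1 <= 0 || w2 <= 0 || w3 <= 0) {
        du[i, j] <- du[j, i] <- sum(diff) / L
        fell_back <- TRUE
      } else {
        du[i, j] <- du[j, i] <- -k1 * log(w1) - k2 * log(w2) - k3 * log(w3)
      }
    }
  }
  if (fell_back)
    warning("TN93 saturation for some pair(s); fell back to p-distance")
  d <- du[idx, idx, drop = FALSE]
  dimnames(d) <- list(names(seqs), names(seqs))
  d
}

#' Geographic distances between populations
#'
#' Great-circle (haversine, km) or planar (decimal-degree Euclidean)
#' distances between population centroids.
#'
#' @param meta Metadata `data.frame` with `population`, `lat`, `lon`.
#' @param method `"greatcircle"` (default) or `"planar"`.
#' @return Symmetric numeric matrix over populations.
#' @export
geographicDistance <- function(meta, method = c("greatcircle", "planar")) {
  method <- match.arg(method)
  if (!all(c("lat", "lon") %in% names(meta))) stop("metadata has no coordinates")
  cen <- stats::aggregate(meta[, c("lat", "lon")],
                          by = list(population = meta$population), mean)
  k <- nrow(cen)
  d <- matrix(0, k, k, dimnames = list(cen$population, cen$population))
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    if (method == "planar") {
      v <- sqrt((cen$lat[i] - cen$lat[j])^2 + (cen$lon[i] - cen$lon[j])^2)
    } else {
      la1 <- cen$lat[i] * pi / 180; la2 <- cen$lat[j] * pi / 180
      dla <- la2 - la1; dlo <- (cen$lon[j] - cen$lon[i]) * pi / 180
      h <- sin(dla / 2)^2 + cos(la1) * cos(la2) * sin(dlo / 2)^2
      v <- 2 * 6371 * asin(pmin(1, sqrt(h)))
    }
    d[i, j] <- d[j, i] <- v
  }
  d
}
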