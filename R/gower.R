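#' Gower dissimilarity between taxa scored for discrete characters
#'
#' For each pair of taxa, the mean per-character distance over the
#' characters scored (non-missing) in both. An unordered character
#' contributes 0 when the two state sets intersect (a shared state —
#' polymorphism counts as potential agreement) and 1 otherwise; an
#' ordered character contributes the minimum `|a - b|` over cross-set
#' state pairs, scaled by `n_states - 1`. Characters missing in either
#' taxon are excluded from that pair's average.
#'
#' @param cm a `charMatrix`.
#' @param chars character ids to include (default: all).
#' @return object of class `gowerDist`: `d` (symmetric matrix in
#'   `[0, 1]`, zero diagonal, `NA` where no character is comparable —
#'   flagged with a warning), `n_comparable` (per-pair counts), `taxa`.
#' @examples
#' m <- matrix(c("0","0", "1","0", "0","1", "2","2", "?","1"), 2, 5,
#'             dimnames = list(c("A","B"), NULL))
#' gowerDissimilarity(characterMatrix(m))$d["A", "B"]   # 0.5
#' @export
gowerDissimilarity <- function(cm, chars = NULL) {
  stopifnot(inherits(cm, "charMatrix"))
  if (is.null(chars)) chars <- cm$meta$id
  j <- match(chars, cm$meta$id)
  if (anyNA(j)) stop("unknown characters: ",
                     paste(chars[is.na(j)], collapse = ", "))
  n <- length(cm$taxa)
  if (n < 2L) stop("need at least 2 taxa")
  D <- matrix(0, n, n); C <- matrix(0L, n, n)
  for (jj in j) {
    col <- cm$cells[, jj]
    len <- lengths(col)
    scored <- len > 0L
    if (sum(scored) < 2L) next
    cmp <- outer(scored, scored, "&")
    if (cm$meta$ordered[jj]) {
      lo <- vapply(col, function(s) if (length(s)) min(s) else NA_real_,
                   numeric(1))
      hi <- vapply(col, function(s) if (length(s)) max(s) else NA_real_,
                   numeric(1))
      gap <- pmax(outer(lo, lo, pmax) - outer(hi, hi, pmin), 0)
      dj <- gap / (cm$meta$n_states[jj] - 1L)
    } else {
      mask <- vapply(col, function(s) sum(bitwShiftL(1L, s)), numeric(1))
      inter <- outer(mask, mask, function(a, b)
        bitwAnd(as.integer(a), as.integer(b)) > 0L)
      dj <- 1 - inter
    }
    dj[!cmp] <- 0
    D <- D + dj
    C <- C + cmp
  }
  d <- D / C
  d[C == 0L] <- NA_real_
  diag(d) <- 0
  if (any(is.na(d[upper.tri(d)])))
    warning("pairs with zero comparable characters: dissimilarity undefined")
  dimnames(d) <- dimnames(C) <- list(cm$taxa, cm$taxa)
  structure(list(d = d, n_comparable = C, taxa = cm$taxa),
            class = "gowerDist")
}

#' @export
print.gowerDist <- function(x, ...) {
  cat("gowerDist over", length(x$taxa), "taxa; mean dissimilarity",
      formatC(mean(x$d[upper.tri(x$d)], na.rm = TRUE), digits = 3,
              format = "f"), "\n")
  if (anyNA(x$d)) cat("  contains undefined (NA) pairs\n")
  invisible(x)
}
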