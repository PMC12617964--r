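#' Dynamic time warping distance between two sequences
#'
#' Classic unconstrained DTW with the symmetric three-way step pattern:
#' local cost `d(i,j) = |x_i - y_j|` (or squared), cumulative
#' `D(i,j) = d(i,j) + min(D(i-1,j), D(i,j-1), D(i-1,j-1))`, no window, no
#' slope constraint. The optimal warping path is recovered by backtracking
#' with a fixed tie-break (diagonal, then vertical, then horizontal) so
#' paths are reproducible; the distance itself is tie-invariant.
#'
#' @param x,y Numeric vectors (or monthly-series data frames), nonempty,
#'   no missing values. Standardize first when units differ
#'   (see [standardize()]).
#' @param cost Local cost: `"abs"` (default) or `"squared"`.
#' @param normalize If `TRUE`, also report the distance divided by the path
#'   length, for comparability across sequence lengths.
#' @return An object of class `dtw_alignment`: `distance`,
#'   `normalized_distance`, `path` (tibble of index pairs from `(1,1)` to
#'   `(n,m)`), `path_length`, `step_pattern`, `cost`.
#' @examples
#' aln <- dtw_distance(c(0, 1, 2, 3), c(0, 0, 1, 2, 3))
#' aln$distance
#' @export
dtw_distance <- function(x, y, cost = c("abs", "squared"), normalize = FALSE) {
  cost <- match.arg(cost)
  xv <- series_values(x)
  yv <- series_values(y)
  if (length(xv) == 0 || length(yv) == 0) {
    abort("sequences must be nonempty", class = "infotrend_dtw_error")
  }
  if (anyNA(xv) || anyNA(yv)) {
    abort("missing values are not allowed in DTW inputs",
          class = "infotrend_dtw_error")
  }
  n <- length(xv)
  m <- length(yv)
  d <- abs(outer(xv, yv, "-"))
  if (cost == "squared") d <- d^2

  D <- matrix(NA_real_, n, m)
  D[1, 1] <- d[1, 1]
  if (n > 1) D[2:n, 1] <- d[1, 1] + cumsum(d[2:n, 1])
  if (m > 1) D[1, 2:m] <- d[1, 1] + cumsum(d[1, 2:m])
  if (n > 1 && m > 1) {
    for (i in 2:n) {
      for (j in 2:m) {
        D[i, j] <- d[i, j] + min(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
      }
    }
  }

  # backtrack from (n, m); candidate order fixes the tie-break
  path <- matrix(NA_integer_, n + m, 2)
  k <- 1L
  i <- n
  j <- m
  path[k, ] <- c(i, j)
  while (i > 1 || j > 1) {
    if (i == 1) {
      j <- j - 1
    } else if (j == 1) {
      i <- i - 1
    } else {
      cand <- c(D[i - 1, j - 1], D[i - 1, j], D[i, j - 1])
      move <- which.min(cand)  # ties: diagonal, then vertical, then horizontal
      if (move == 1) {
        i <- i - 1
        j <- j - 1
      } else if (move == 2) {
        i <- i - 1
      } else {
        j <- j - 1
      }
    }
    k <- k + 1L
    path[k, ] <- c(i, j)
  }
  path <- path[k:1, , drop = FALSE]
  structure(
    list(
      distance = D[n, m],
      normalized_distance = if (normalize) D[n, m] / k else NA_real_,
      path = tibble::tibble(i = as.integer(path[, 1]), j = as.integer(path[, 2])),
      path_length = as.integer(k),
      step_pattern = "symmetric (diagonal/vertical/horizontal)",
      cost = cost
    ),
    class = "dtw_alignment"
  )
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat(sprintf("<dtw_alignment> distance = %.4g (%s cost), path length %d\n",
              x$distance, x$cost, x$path_length))
  invisible(x)
}

#' @rdname dtw_distance
#' @method tidy dtw_alignment
#' @export
tidy.dtw_alignment <- function(x, ...) {
  x$path
}

#' @rdname dtw_distance
#' @method glance dtw_alignment
#' @export
glance.dtw_alignment <- function(x, ...) {
  tibble::tibble(distance = x$distance,
                 normalized.distance = x$normalized_distance,
                 path.length = x$path_length, cost = x$cost)
}

#' Rank environmental parameters by DTW alignment with the RSV series
#'
#' Computes the DTW distance between the standardized RSV series and each
#' standardized environmental parameter that passed the Spearman screen
#' (significance tier other than `"none"`), and ranks parameters by
#' ascending distance — the smallest distance indicates the strongest
#' temporal alignment. Ties are broken by parameter name so the ranking does
#' not depend on input order.
#'
#' @param panel A preprocessed wide panel (no missing cells).
#' @param rsv The RSV monthly-series data frame on the same date grid.
#' @param screen The correlation table from [correlate_panel()].
#' @param cost,normalize Passed to [dtw_distance()]; ranking uses the
#'   normalized distance when `normalize = TRUE`.
#' @return A tibble ordered by rank: `parameter`, `dtw_distance`,
#'   `path_length`, `rank`. Empty (with a message) when no parameter is
#'   significant.
#' @export
rank_alignment <- function(panel, rsv, screen, cost = "abs", normalize = FALSE) {
  stopifnot(is.data.frame(screen), all(c("parameter", "tier") %in% names(screen)))
  sig <- screen$parameter[screen$tier != "none"]
  sig <- intersect(panel_parameters(panel), sig)
  if (length(sig) == 0) {
    inform("no parameters significant in the correlation screen; empty DTW ranking")
    return(tibble::tibble(parameter = character(), dtw_distance = numeric(),
                          path_length = integer(), rank = integer()))
  }
  rsv_z <- zscore(validate_series(rsv, arg = "rsv")$value, label = "rsv")
  out <- purrr::map(sig, function(p) {
    aln <- dtw_distance(rsv_z, zscore(panel[[p]], label = p),
                        cost = cost, normalize = normalize)
    tibble::tibble(
      parameter = p,
      dtw_distance = if (normalize) aln$normalized_distance else aln$distance,
      path_length = aln$path_length
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(dtw_distance, parameter) |>
    dplyr::mutate(rank = dplyr::row_number())
  out
}
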