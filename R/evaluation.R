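#' Rank-1 distance to the nearest reference position
#'
#' Euclidean distance from the top-ranked predicted site to the nearest
#' reference (experimentally determined) ion position. With several
#' reference positions the closest one is used, which credits a correct
#' prediction of any of the ions around the same structure.
#'
#' @param pred An `"ion_sites"` object, or an m x 3 matrix of predicted
#'   positions in rank order.
#' @param refs An r x 3 matrix (or 3-vector) of reference positions.
#' @return Distance in Angstrom; `NA_real_` (with a warning) when there are
#'   no predictions.
#' @export
rank1_distance <- function(pred, refs) {
  p <- pred_matrix(pred)
  refs <- ref_matrix(refs)
  if (nrow(p) == 0L) {
    warning("no predicted sites: rank-1 distance undefined", call. = FALSE)
    return(NA_real_)
  }
  min(sqrt(colSums((t(refs) - p[1, ])^2)))
}

#' Minimum distance over the top-k predictions
#'
#' The shortest Euclidean distance between any of the first `top_k`
#' predicted positions (independent of rank) and any reference position,
#' plus which rank achieved it.
#'
#' @param pred An `"ion_sites"` object or m x 3 position matrix in rank
#'   order.
#' @param refs Reference positions (r x 3 matrix or 3-vector).
#' @param top_k How many leading predictions to consider (default 10).
#' @return An object of class `"site_eval"`: list with `d_min`,
#'   `matched_rank`, `rank1_distance`, and `per_reference` (data frame with
#'   one row per reference: its best rank among the top-k and the distance).
#' @export
d_min <- function(pred, refs, top_k = 10) {
  p <- pred_matrix(pred)
  refs <- ref_matrix(refs)
  if (nrow(p) == 0L) {
    warning("no predicted sites: d_min undefined", call. = FALSE)
    return(structure(list(d_min = NA_real_, matched_rank = NA_integer_,
                          rank1_distance = NA_real_,
                          per_reference = data.frame()),
                     class = "site_eval"))
  }
  k <- min(top_k, nrow(p))
  pk <- p[seq_len(k), , drop = FALSE]
  dm <- matrix(NA_real_, nrow = k, ncol = nrow(refs))
  for (j in seq_len(nrow(refs)))
    dm[, j] <- sqrt(colSums((t(pk) - refs[j, ])^2))
  best <- which(dm == min(dm), arr.ind = TRUE)[1, ]
  per_ref <- data.frame(
    reference = seq_len(nrow(refs)),
    best_rank = apply(dm, 2, which.min),
    distance = apply(dm, 2, min)
  )
  structure(list(d_min = min(dm), matched_rank = as.integer(best[1]),
                 rank1_distance = min(dm[1, ]), per_reference = per_ref),
            class = "site_eval")
}

#' @export
print.site_eval <- function(x, ...) {
  cat(sprintf("d_min = %.3f A (rank %d); rank-1 distance = %.3f A\n",
              x$d_min, x$matched_rank, x$rank1_distance))
  if (nrow(x$per_reference) > 1L) {
    cat("per-reference best matches:\n")
    print(x$per_reference, row.names = FALSE)
  }
  invisible(x)
}

#' Best-of-N comparison of two prediction sets
#'
#' For each method, the minimum distance to any reference among its first
#' `n` outputs. This is the protocol for comparing a ranked predictor with
#' an unranked placer that emits N ions: each method is credited with its
#' best ion among the first N.
#'
#' @param predA,predB Prediction sets (`"ion_sites"` objects or m x 3
#'   matrices in output order).
#' @param refs Reference positions.
#' @param n How many leading outputs to consider per method.
#' @return Named numeric vector `c(A = , B = )` of distances in Angstrom.
#' @export
best_of_n <- function(predA, predB, refs, n) {
  stopifnot(n >= 1)
  refs <- ref_matrix(refs)
  one <- function(pred) {
    p <- pred_matrix(pred)
    if (nrow(p) == 0L) return(NA_real_)
    if (nrow(p) < n)
      message(sprintf("method has only %d of %d requested outputs; using all",
                      nrow(p), n))
    k <- min(n, nrow(p))
    min(vapply(seq_len(k), function(i)
      min(sqrt(colSums((t(refs) - p[i, ])^2))), numeric(1)))
  }
  c(A = one(predA), B = one(predB))
}

#' Read a reference-ion position table
#'
#' Accepts either a whitespace/tab-separated 3-column (x y z) table, or a
#' PDB/PQR file whose HETATM records carry the reference ions.
#'
#' @param path Input file.
#' @return An r x 3 matrix of positions.
#' @export
read_reference_positions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^(ATOM|HETATM)", lines))) {
    s <- read_pqr(path)
    het <- s$atoms[s$atoms$record == "HETATM", , drop = FALSE]
    if (nrow(het) == 0L) het <- s$atoms
    return(unname(cbind(het$x, het$y, het$z)))
  }
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "[[:space:]]+"),
                             function(t) as.numeric(t[1:3])))
  if (anyNA(m)) stop("malformed reference position table", call. = FALSE)
  m
}

pred_matrix <- function(pred) {
  if (inherits(pred, "ion_sites"))
    return(unname(as.matrix(pred$sites[, c("x", "y", "z")])))
  if (is.null(pred) || length(pred) == 0L) return(matrix(numeric(0), ncol = 3))
  if (!is.matrix(pred)) pred <- matrix(pred, ncol = 3)
  unname(pred)
}

ref_matrix <- function(refs) {
  if (!is.matrix(refs)) refs <- matrix(refs, ncol = 3)
  stopifnot(nrow(refs) >= 1)
  unname(refs)
}
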