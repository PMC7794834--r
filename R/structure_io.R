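#' Read a PQR structure
#'
#' Parses ATOM and HETATM records from a PQR file. Both fixed-column and
#' free-whitespace PQR dialects are accepted: the last five whitespace
#' separated numeric tokens of each record are taken as x, y, z (Angstrom),
#' partial charge (e) and van der Waals radius (Angstrom). The chain
#' identifier is optional and detected by token count.
#'
#' @param source Path to a PQR file, or a character vector of PQR lines.
#' @param label Structure label; defaults to the file name.
#' @return An object of class `"pqr"`: a list with `atoms` (a data frame with
#'   columns `record`, `serial`, `name`, `resname`, `chain`, `resno`, `x`,
#'   `y`, `z`, `charge`, `radius`) and `label`.
#' @seealso [write_pqr()], [strip_hetero()], [net_charge()]
#' @examples
#' s <- read_pqr(c("ATOM 1 N ALA 1 0.0 0.0 0.0 -0.3 1.55"))
#' net_charge(s)
#' @export
read_pqr <- function(source, label = NULL) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source)) {
    lines <- readLines(source, warn = FALSE)
    if (is.null(label)) label <- basename(source)
  } else {
    lines <- unlist(strsplit(as.character(source), "\n", fixed = TRUE))
    if (is.null(label)) label <- "structure"
  }
  is_rec <- grepl("^(ATOM|HETATM)", lines)
  recs <- lines[is_rec]
  lineno <- which(is_rec)
  if (length(recs) == 0L)
    stop("empty structure: no ATOM/HETATM records found", call. = FALSE)

  n <- length(recs)
  out <- list(
    record = character(n), serial = integer(n), name = character(n),
    resname = character(n), chain = character(n), resno = integer(n),
    x = numeric(n), y = numeric(n), z = numeric(n),
    charge = numeric(n), radius = numeric(n)
  )
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(recs[i]), "[[:space:]]+")[[1]]
    if (length(tok) < 9L)
      stop(sprintf("PQR parse error at line %d: too few fields", lineno[i]),
           call. = FALSE)
    num <- suppressWarnings(as.numeric(tok[(length(tok) - 4L):length(tok)]))
    if (anyNA(num))
      stop(sprintf("PQR parse error at line %d: non-numeric coordinate/charge/radius field",
                   lineno[i]), call. = FALSE)
    out$record[i] <- tok[1]
    out$serial[i] <- suppressWarnings(as.integer(tok[2]))
    if (is.na(out$serial[i])) out$serial[i] <- i
    out$name[i] <- tok[3]
    out$resname[i] <- tok[4]
    # chain id present iff a non-numeric token sits between resname and resno
    head_len <- length(tok) - 5L      # tokens before the numeric tail
    if (head_len >= 6L) {
      out$chain[i] <- tok[5]
      out$resno[i] <- suppressWarnings(as.integer(tok[6]))
    } else {
      out$chain[i] <- ""
      out$resno[i] <- suppressWarnings(as.integer(tok[5]))
    }
    if (is.na(out$resno[i])) out$resno[i] <- 1L
    out$x[i] <- num[1]; out$y[i] <- num[2]; out$z[i] <- num[3]
    out$charge[i] <- num[4]; out$radius[i] <- num[5]
  }
  atoms <- as.data.frame(out, stringsAsFactors = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("PQR parse error: non-finite coordinates", call. = FALSE)
  if (any(atoms$radius <= 0))
    stop("PQR parse error: atom radius must be positive", call. = FALSE)
  new_structure(atoms, label)
}

new_structure <- function(atoms, label = "structure") {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  structure(list(atoms = atoms, label = label), class = "pqr")
}

#' Write a structure to a PQR file
#'
#' @param s A `"pqr"` structure.
#' @param path Output path; `""` returns the lines invisibly without writing.
#' @param fixed Use PDB-style fixed columns (8.3f coordinates) instead of the
#'   default high-precision whitespace layout. Fixed columns are what strict
#'   PDB-derived readers expect; the default preserves coordinates to 1e-6.
#' @return The formatted lines, invisibly.
#' @export
write_pqr <- function(s, path = "", fixed = FALSE) {
  a <- s$atoms
  if (fixed) {
    ch <- ifelse(nzchar(a$chain), substr(a$chain, 1, 1), " ")
    lines <- sprintf("%-6s%5d  %-3s %-4s%1s%4d    %8.3f%8.3f%8.3f %7.4f %6.4f",
                     a$record, a$serial, a$name, a$resname, ch, a$resno,
                     a$x, a$y, a$z, a$charge, a$radius)
  } else {
    chain <- ifelse(nzchar(a$chain), paste0(a$chain, " "), "")
    lines <- sprintf("%-6s %4d %-4s %-4s %s%4d %11.6f %11.6f %11.6f %9.6f %8.6f",
                     a$record, a$serial, a$name, a$resname, chain, a$resno,
                     a$x, a$y, a$z, a$charge, a$radius)
  }
  if (nzchar(path)) writeLines(c(lines, "END"), path)
  invisible(lines)
}

#' Remove hetero atoms from a structure
#'
#' Keeps only ATOM records, dropping HETATM records (pre-existing ions,
#' waters, ligands) so the prediction sees the bare polymer. Idempotent.
#'
#' @param s A `"pqr"` structure.
#' @return A `"pqr"` structure with HETATM records removed.
#' @export
strip_hetero <- function(s) {
  stopifnot(inherits(s, "pqr"))
  keep <- s$atoms$record == "ATOM"
  if (!any(keep))
    stop("empty structure: all atoms are HETATM records", call. = FALSE)
  new_structure(s$atoms[keep, , drop = FALSE], s$label)
}

#' Net charge of a structure
#'
#' @param s A `"pqr"` structure.
#' @return Sum of atomic partial charges, in units of e.
#' @export
net_charge <- function(s) {
  stopifnot(inherits(s, "pqr"))
  sum(s$atoms$charge)
}

#' @export
print.pqr <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("PQR structure '%s': %d atoms (%d ATOM, %d HETATM)\n",
              x$label, nrow(a), sum(a$record == "ATOM"),
              sum(a$record == "HETATM")))
  cat(sprintf("  net charge %+.3f e; extent %.1f x %.1f x %.1f A\n",
              sum(a$charge), diff(range(a$x)), diff(range(a$y)),
              diff(range(a$z))))
  invisible(x)
}

#' @export
as.data.frame.pqr <- function(x, ...) x$atoms

# n x 3 coordinate matrix
coords <- function(s) cbind(s$atoms$x, s$atoms$y, s$atoms$z)
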