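#' Read a PQR file as a charge set
#'
#' Parses whitespace-delimited ATOM/HETATM records. The expected fields are
#' record, serial, atom name, residue name, optional chain id, residue
#' number, then x, y, z, charge, radius; the radius column is parsed but
#' unused. REMARK/comment and other records are skipped. Malformed ATOM
#' lines are reported with their line numbers.
#'
#' @param path Path to a PQR file.
#' @return A [charge_set()].
#' @export
read_pqr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(grepl("^(ATOM|HETATM)", lines))
  if (length(keep) == 0) stop("no ATOM/HETATM records in ", path, call. = FALSE)
  rows <- purrr::map(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    # x y z q r are the trailing five fields whether or not a chain id is present
    if (!length(f) %in% c(10, 11)) {
      stop(sprintf("line %d: expected 10 or 11 fields, got %d", i, length(f)),
        call. = FALSE
      )
    }
    num <- suppressWarnings(as.numeric(utils::tail(f, 5)))
    if (anyNA(num)) {
      stop(sprintf("line %d: non-numeric coordinate/charge/radius field", i),
        call. = FALSE
      )
    }
    tibble::tibble(x = num[1], y = num[2], z = num[3], q = num[4])
  })
  charge_set(dplyr::bind_rows(rows), label = basename(path))
}

#' Read and write the plain "xyzq" format
#'
#' Four whitespace-separated columns `x y z q` (Angstrom and e), `#` starts a
#' comment. `write_xyzq()` emits a fixed 9-decimal format so that files
#' round-trip losslessly at the precision force fields use.
#'
#' @param path File path.
#' @param cs A [charge_set()].
#' @return `read_xyzq()` returns a [charge_set()]; `write_xyzq()` returns
#'   `path` invisibly.
#' @export
read_xyzq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no data rows in ", path, call. = FALSE)
  rows <- purrr::map(lines, function(l) {
    f <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]]))
    if (length(f) != 4 || anyNA(f)) {
      stop("xyzq rows must have 4 numeric columns: ", l, call. = FALSE)
    }
    f
  })
  m <- do.call(rbind, rows)
  colnames(m) <- c("x", "y", "z", "q")
  charge_set(m, label = basename(path))
}

#' @rdname read_xyzq
#' @export
write_xyzq <- function(cs, path) {
  cs <- as_charge_set(cs)
  header <- sprintf(
    "# xyzq: x y z [Angstrom], q [e]; %d charges, net %.9f e",
    nrow(cs), sum(cs$q)
  )
  body <- sprintf("%15.9f %15.9f %15.9f %15.9f", cs$x, cs$y, cs$z, cs$q)
  writeLines(c(header, body), path)
  invisible(path)
}
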