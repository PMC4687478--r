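#' Read and write potential curve files
#'
#' Curves are stored as UTF-8 text: `#`-prefixed header lines carrying
#' `R0_angstrom=<float>` and `label=<text>`, followed by two
#' whitespace-separated numeric columns (`q_angstrom`,
#' `energy_kcal_per_mol`). The round trip preserves values to 12
#' significant digits. Rows arriving out of order are sorted with a
#' warning; duplicated `q`, non-numeric rows, or a missing
#' `R0_angstrom` header are format errors reported with line numbers.
#'
#' @param path File path.
#' @return `read_curve()` returns a `vibhb_curve`; `write_curve()`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".dat")
#' write_curve(make_pyp_crystal_fixture(), f)
#' read_curve(f)
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("curve file not found: ", path),
          class = "vibhb_format_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  r0 <- NULL
  label <- ""
  q <- numeric(0)
  energy <- numeric(0)
  line_no <- integer(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      body <- trimws(sub("^#+\\s*", "", ln))
      if (grepl("^R0_angstrom\\s*=", body)) {
        r0 <- suppressWarnings(
          as.numeric(trimws(sub("^R0_angstrom\\s*=", "", body)))
        )
        if (is.na(r0)) {
          abort(sprintf("line %d: unparseable R0_angstrom header", i),
                class = "vibhb_format_error")
        }
      } else if (grepl("^label\\s*=", body)) {
        label <- trimws(sub("^label\\s*=", "", body))
      }
      next
    }
    fields <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(fields) != 2L) {
      abort(sprintf("line %d: expected 2 columns, found %d",
                    i, length(fields)),
            class = "vibhb_format_error")
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      abort(sprintf("line %d: non-numeric row '%s'", i, ln),
            class = "vibhb_format_error")
    }
    q <- c(q, vals[[1]])
    energy <- c(energy, vals[[2]])
    line_no <- c(line_no, i)
  }
  if (is.null(r0)) {
    abort("missing required header '# R0_angstrom=<float>'",
          class = "vibhb_format_error")
  }
  if (anyDuplicated(q)) {
    dup <- line_no[duplicated(q)][[1]]
    abort(sprintf("line %d: duplicated q value", dup),
          class = "vibhb_format_error")
  }
  if (is.unsorted(q, strictly = TRUE)) {
    warn("curve rows were not sorted by q; sorting on read",
         class = "vibhb_unsorted_warning")
    ord <- order(q)
    q <- q[ord]
    energy <- energy[ord]
  }
  potential_curve(q, energy, r0 = r0, label = label)
}

#' @rdname read_curve
#' @param curve A `vibhb_curve`.
#' @param digits Significant digits written (default 15, comfortably
#'   beyond the 12-digit round-trip contract).
#' @export
write_curve <- function(curve, path, digits = 15L) {
  curve <- validate_curve(curve)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# R0_angstrom=%s", format(curve_r0(curve), digits = digits)),
    sprintf("# label=%s", curve_label(curve)),
    "# q_angstrom energy_kcal_per_mol",
    sprintf("%.*g %.*g", digits, curve$q, digits, curve$energy)
  ), con)
  invisible(path)
}

#' Export a curve as CSV (for plotting in other tools)
#'
#' @inheritParams write_curve
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  curve <- validate_curve(curve)
  out <- data.frame(
    q_angstrom = curve$q,
    R_angstrom = bond_length(curve),
    energy_kcal_per_mol = curve$energy
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
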