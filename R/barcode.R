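#' Persistence barcodes
#'
#' A degree-n barcode is a multiset of (birth, death) intervals ("bars")
#' summarising the lifespan of homological features (components, loops,
#' voids for n = 0, 1, 2) along a filtration, with coefficients in the field
#' of two elements. Depth filtrations are in `mm_depth` units (distance below
#' the top of the bounding box); alpha filtrations in `mm_radius` units
#' (thickening radius). Essential features have death `Inf`; zero-persistence
#' pairs (birth == death) are dropped.
#'
#' @param degree non-negative integer homology degree.
#' @param bars two-column numeric matrix (birth, death), possibly 0-row.
#' @param units `"mm_depth"` or `"mm_radius"`.
#' @param max_filtration largest filtration value of the generating
#'   construction; used as the default cap for essential bars.
#' @param provenance character log.
#' @return a `barcode` object.
#' @export
barcode <- function(degree, bars, units = c("mm_depth", "mm_radius"),
                    max_filtration = NA_real_, provenance = character()) {
  units <- match.arg(units)
  bars <- matrix(as.numeric(bars), ncol = 2,
                 dimnames = list(NULL, c("birth", "death")))
  if (nrow(bars) && any(bars[, 2] < bars[, 1]))
    stop("invalid barcode: death before birth")
  keep <- !(bars[, 2] == bars[, 1])
  bars <- bars[keep, , drop = FALSE]
  ord <- order(bars[, 1], bars[, 2])
  structure(list(degree = as.integer(degree), bars = bars[ord, , drop = FALSE],
                 units = units, max_filtration = max_filtration,
                 provenance = provenance),
            class = "barcode")
}

#' @export
print.barcode <- function(x, ...) {
  cat(sprintf("degree-%d barcode (%s): %d bars (%d essential)\n", x$degree,
              x$units, nrow(x$bars), sum(is.infinite(x$bars[, 2]))))
  invisible(x)
}

n_bars <- function(b, finite = NA) {
  if (is.na(finite)) return(nrow(b$bars))
  if (finite) sum(is.finite(b$bars[, 2])) else sum(is.infinite(b$bars[, 2]))
}

#' Total persistence of a barcode
#'
#' The sum of bar lengths death - birth. For degree-1 alpha barcodes on
#' centerline nodes this sum is the branch-to-branch proximity.
#'
#' @param b a `barcode` with finite (or capped, see [cap_barcode()]) bars.
#' @return non-negative real.
#' @export
total_persistence <- function(b) {
  if (nrow(b$bars) == 0) return(0)
  if (any(is.infinite(b$bars[, 2])))
    stop("barcode has essential bars; cap them first (cap_barcode)")
  sum(b$bars[, 2] - b$bars[, 1])
}

#' Cap essential bars
#'
#' Replaces infinite deaths by a finite cap before distance or total
#' persistence computations. The default cap is the maximum filtration value
#' of the generating construction (for height filtrations, the depth of the
#' bounding box). The cap is recorded in the barcode provenance.
#'
#' @param b a `barcode`.
#' @param cap finite cap value; defaults to `b$max_filtration`.
#' @return the capped `barcode`.
#' @export
cap_barcode <- function(b, cap = NULL) {
  cap <- cap %||% b$max_filtration
  if (!is.finite(cap))
    stop("no finite cap available: supply `cap` or a max_filtration")
  bars <- b$bars
  inf <- is.infinite(bars[, 2])
  bars[inf, 2] <- pmax(cap, bars[inf, 1])
  barcode(b$degree, bars, b$units, max_filtration = b$max_filtration,
          provenance = c(b$provenance, sprintf("capped_at %.17g", cap)))
}

#' Write a barcode to a plain-text diagram file
#'
#' One "birth death" pair per line, `inf` for essential deaths, with a `#`
#' header recording degree, units and (when present) the max filtration
#' value. Round trips through [read_diagram()].
#'
#' @param b a `barcode`.
#' @param path output file.
#' @export
write_diagram <- function(b, path) {
  hdr <- c(sprintf("# degree: %d", b$degree), sprintf("# units: %s", b$units))
  if (is.finite(b$max_filtration))
    hdr <- c(hdr, sprintf("# max_filtration: %.17g", b$max_filtration))
  rows <- apply(b$bars, 1, function(r)
    paste(sprintf("%.17g", r[1]),
          if (is.infinite(r[2])) "inf" else sprintf("%.17g", r[2])))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a barcode from a plain-text diagram file
#'
#' @param path file written by [write_diagram()] (or compatible).
#' @return a `barcode`.
#' @export
read_diagram <- function(path) {
  lines <- readLines(path)
  grab <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), lines, value = TRUE)
    if (length(m)) trimws(sub(paste0("^#\\s*", key, ":"), "", m[1])) else NA
  }
  degree <- suppressWarnings(as.integer(grab("degree")))
  if (is.na(degree)) stop("parse error: missing '# degree:' header in ", path)
  units <- grab("units")
  if (is.na(units)) units <- "mm_depth"
  maxf <- suppressWarnings(as.numeric(grab("max_filtration")))
  body <- lines[!grepl("^\\s*#", lines) & grepl("\\S", lines)]
  if (length(body) == 0)
    return(barcode(degree, matrix(numeric(0), ncol = 2), units,
                   max_filtration = maxf))
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(parts) != 2)
  if (length(bad)) stop("parse error at line ", bad[1], ": expected 2 fields")
  num <- function(s) ifelse(tolower(s) == "inf", Inf,
                            suppressWarnings(as.numeric(s)))
  m <- matrix(num(unlist(parts)), ncol = 2, byrow = TRUE)
  if (anyNA(m))
    stop("parse error: non-numeric bar endpoint in ", path)
  barcode(degree, m, units, max_filtration = maxf)
}
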