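#' @useDynLib lungtda, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-item sub-seed derived from a master seed; kept < 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483629) + 1L
}

find_python <- function() {
  py <- Sys.getenv("LUNGTDA_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("no python interpreter found on PATH (needed for Delaunay triangulation)")
  py
}

# Delaunay triangulation of an n x d point matrix (d in 1..3) through qhull.
# Returns an m x (d+1) matrix of 1-based vertex indices.
delaunay_simplices <- function(pts) {
  d <- ncol(pts)
  script <- system.file("python", "delaunay_simplices.py", package = "lungtda",
                        mustWork = TRUE)
  fin <- tempfile("pts", fileext = ".txt")
  fout <- tempfile("simp", fileext = ".txt")
  on.exit(unlink(c(fin, fout)))
  utils::write.table(format(pts, digits = 17, scientific = TRUE, trim = TRUE),
                     fin, row.names = FALSE, col.names = FALSE, quote = FALSE)
  status <- system2(find_python(), c(shQuote(script), shQuote(fin), shQuote(fout)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) || !file.exists(fout))
    stop("Delaunay triangulation failed: ", paste(status, collapse = " "))
  m <- as.matrix(utils::read.table(fout))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  if (ncol(m) != d + 1) stop("unexpected Delaunay output dimension")
  m
}
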