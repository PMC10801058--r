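#' @importFrom jsonlite toJSON fromJSON write_json read_json base64_enc base64_dec
#' @importFrom stats runif
#' @importFrom utils head tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

# Structured conditions: every package error carries class "fs_error" plus a
# specific subclass so callers (and tests) can dispatch on failure kind.
fs_abort <- function(subclass, message, data = list()) {
  cond <- structure(
    class = c(paste0("fs_error_", subclass), "fs_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
  stop(cond)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == as.integer(x)
}

#' Derive a child seed from a root seed and string labels
#'
#' Polynomial string hash folded with the root seed, reduced modulo a prime
#' below 2^31 so the result is always a valid R integer seed. Used to give
#' every (provider, entity) its own independent random stream, so that the
#' insertion order of entities cannot change generated values.
#'
#' @param root integer root seed.
#' @param ... character labels mixed into the derived seed.
#' @return a single integer seed.
#' @export
derive_seed <- function(root, ...) {
  p <- 2147483587 # largest prime < 2^31 - 60
  labels <- paste(vapply(list(...), as.character, ""), collapse = "\x1f")
  h <- as.numeric(root) %% p
  for (b in utf8ToInt(labels)) h <- (h * 131 + b) %% p
  as.integer(h)
}

#' Create an explicit random stream
#'
#' Wraps an independent Mersenne-Twister state so synthetic-data generation
#' never touches (or depends on) the session's global random state. All
#' generator draws go through `rs_eval()` and helpers, which swap the stream
#' state in and out of `.Random.seed` around the draw.
#'
#' @param seed integer seed initialising the stream.
#' @return an object of class `fs_random_stream`.
#' @export
random_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  st <- new.env(parent = emptyenv())
  st$seed <- as.integer(seed %% .Machine$integer.max)
  st$state <- NULL
  class(st) <- "fs_random_stream"
  st
}

#' Evaluate a thunk under a stream's private random state
#' @param stream an `fs_random_stream`.
#' @param thunk a zero-argument function performing random draws.
#' @return the thunk's value.
#' @export
rs_eval <- function(stream, thunk) {
  stopifnot(inherits(stream, "fs_random_stream"))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    stream$state <- get(".Random.seed", envir = genv, inherits = FALSE)
    if (had) assign(".Random.seed", old, envir = genv) else rm(".Random.seed", envir = genv)
  })
  if (is.null(stream$state)) set.seed(stream$seed) else assign(".Random.seed", stream$state, envir = genv)
  thunk()
}

rs_int <- function(stream, min, max) {
  # sample.int avoids sample()'s scalar-x pitfall when min == max
  rs_eval(stream, function() as.integer(min + sample.int(max - min + 1L, 1L) - 1L))
}

rs_unif <- function(stream, min = 0, max = 1, n = 1L) {
  rs_eval(stream, function() runif(n, min, max))
}

rs_pick <- function(stream, x) rs_eval(stream, function() x[[sample.int(length(x), 1L)]])

rs_chars <- function(stream, n, alphabet = c(letters, LETTERS, 0:9)) {
  rs_eval(stream, function() paste(sample(alphabet, n, replace = TRUE), collapse = ""))
}

rs_hex <- function(stream, n) rs_chars(stream, n, alphabet = c(0:9, letters[1:6]))

rs_flip <- function(stream, prob) rs_eval(stream, function() runif(1) < prob)

#' MD5 digest of a character string
#' @param x a character scalar.
#' @return hex digest string.
#' @export
md5_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(charToRaw(paste(x, collapse = "\n")), f)
  unname(tools::md5sum(f))
}

md5_raw <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(x, f)
  unname(tools::md5sum(f))
}

# Content digest of a directory tree: digest of "relpath md5" lines over all
# files, sorted by path, so snapshots compare byte-for-byte.
md5_tree <- function(dir) {
  if (!dir.exists(dir)) return(md5_string(""))
  files <- sort(list.files(dir, recursive = TRUE, all.files = TRUE, no.. = TRUE))
  files <- files[file.exists(file.path(dir, files)) & !dir.exists(file.path(dir, files))]
  if (!length(files)) return(md5_string(""))
  sums <- tools::md5sum(file.path(dir, files))
  md5_string(paste(files, unname(sums), collapse = "\n"))
}

# Canonical JSON used for structural digests and round-trip comparisons.
canonical_json <- function(x) {
  as.character(toJSON(x, auto_unbox = TRUE, digits = NA, null = "null", na = "null"))
}

read_ndjson <- function(path) {
  if (!file.exists(path) || file.info(path)$size == 0) return(list())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lapply(lines, function(l) fromJSON(l, simplifyVector = FALSE))
}

append_ndjson <- function(path, record) {
  cat(canonical_json(record), "\n", sep = "", file = path, append = TRUE)
}

wait_until <- function(predicate, timeout = 15, poll = 0.03) {
  t0 <- Sys.time()
  while (as.numeric(difftime(Sys.time(), t0, units = "secs")) < timeout) {
    if (isTRUE(predicate())) return(TRUE)
    Sys.sleep(poll)
  }
  isTRUE(predicate())
}
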