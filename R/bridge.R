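## Bridge to the bundled Python worker (RDKit + scikit-learn).
##
## A single worker process is started lazily and spoken to over a
## localhost socket with newline-delimited JSON.  If the socket cannot be
## established (e.g. a sandbox without loopback networking) every call
## falls back to a one-shot subprocess, which is slower but equivalent.
## Canonicalisation and fingerprint results are memoised per SMILES
## string because training loops re-score overlapping molecule sets.

.bridge <- new.env(parent = emptyenv())

.bridge_reset <- function() {
  .bridge$con <- NULL
  .bridge$pid <- NULL
  .bridge$mode <- NULL
  .bridge$cache_parse <- new.env(parent = emptyenv(), hash = TRUE)
  .bridge$cache_fp <- new.env(parent = emptyenv(), hash = TRUE)
  .bridge$cache_q <- new.env(parent = emptyenv(), hash = TRUE)
}

.onLoad <- function(libname, pkgname) {
  .bridge_reset()
}

.onUnload <- function(libpath) {
  bridge_stop()
}

#' Locate the Python interpreter used by the chemistry worker
#'
#' Honours the `SMILESRL_PYTHON` environment variable, then falls back to
#' `python` / `python3` on the PATH.
#' @return Path to the interpreter.
#' @keywords internal
bridge_python <- function() {
  cand <- Sys.getenv("SMILESRL_PYTHON", "")
  if (nzchar(cand)) return(cand)
  for (p in c("python", "python3")) {
    hit <- Sys.which(p)
    if (nzchar(hit)) return(unname(hit))
  }
  stop("no python interpreter found; set SMILESRL_PYTHON", call. = FALSE)
}

.bridge_script <- function() {
  path <- system.file("python", "worker.py", package = "smilesrl")
  if (!nzchar(path)) stop("worker.py not found in installed package")
  path
}

.bridge_start <- function() {
  portfile <- tempfile("smilesrl-port-")
  system2(bridge_python(), c(.bridge_script(), portfile),
          wait = FALSE, stdout = FALSE, stderr = FALSE)
  port <- NA_integer_
  for (i in seq_len(300)) {   # up to 30 s for a cold rdkit import
    if (file.exists(portfile)) {
      txt <- tryCatch(readLines(portfile, warn = FALSE), error = function(e) "")
      if (length(txt) && nzchar(txt[1])) { port <- as.integer(txt[1]); break }
    }
    Sys.sleep(0.1)
  }
  if (is.na(port)) return(FALSE)
  con <- tryCatch(
    socketConnection("127.0.0.1", port, blocking = TRUE, open = "r+b",
                     timeout = 3600),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(con)) return(FALSE)
  .bridge$con <- con
  ok <- tryCatch({
    writeLines('{"op":"ping"}', con)
    ans <- readLines(con, n = 1L)
    length(ans) == 1L && grepl("pong", ans, fixed = TRUE)
  }, error = function(e) FALSE)
  if (!ok) {
    try(close(con), silent = TRUE)
    .bridge$con <- NULL
    return(FALSE)
  }
  TRUE
}

.bridge_ensure <- function() {
  if (!is.null(.bridge$mode)) return(.bridge$mode)
  mode <- if (isTRUE(getOption("smilesrl.no_socket", FALSE))) "oneshot"
          else if (.bridge_start()) "socket" else "oneshot"
  .bridge$mode <- mode
  mode
}

#' Stop the background chemistry worker
#'
#' Closes the socket (the worker exits when its connection drops) and
#' clears the memoisation caches.  Called automatically on unload; safe
#' to call at any time — the worker restarts on the next request.
#' @return Invisibly `NULL`.
#' @export
bridge_stop <- function() {
  if (!is.null(.bridge$con)) {
    try({
      writeLines('{"op":"shutdown"}', .bridge$con)
      close(.bridge$con)
    }, silent = TRUE)
  }
  .bridge_reset()
  invisible(NULL)
}

.bridge_call <- function(op, args = list()) {
  req <- jsonlite::toJSON(c(list(op = op), args), auto_unbox = TRUE,
                          digits = NA, null = "null")
  mode <- .bridge_ensure()
  line <- NULL
  if (mode == "socket") {
    line <- tryCatch({
      writeLines(req, .bridge$con)
      readLines(.bridge$con, n = 1L)
    }, error = function(e) NULL)
    if (is.null(line) || !length(line)) {
      # worker died; restart once, then fall back to one-shot
      bridge_stop()
      if (.bridge_start()) {
        .bridge$mode <- "socket"
        writeLines(req, .bridge$con)
        line <- readLines(.bridge$con, n = 1L)
      } else {
        .bridge$mode <- "oneshot"
        mode <- "oneshot"
      }
    }
  }
  if (mode == "oneshot") {
    line <- system2(bridge_python(), c(.bridge_script(), "--oneshot"),
                    input = req, stdout = TRUE, stderr = FALSE)
    line <- line[length(line)]
  }
  ans <- jsonlite::fromJSON(line, simplifyVector = FALSE)
  if (!isTRUE(ans$ok)) stop("chemistry worker error: ", ans$error, call. = FALSE)
  ans$value
}

## ---- memoised chemistry wrappers ----------------------------------------

#' Parse SMILES strings with RDKit
#'
#' @param smiles Character vector.
#' @return A data.frame with columns `smiles`, `valid` (logical) and
#'   `canonical` (canonical SMILES, `NA` for unparseable input).
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles))
  key <- paste0("s:", smiles)   # env keys must be non-empty
  miss <- !vapply(key, exists, logical(1), envir = .bridge$cache_parse,
                  inherits = FALSE)
  todo <- unique(smiles[miss])
  if (length(todo)) {
    val <- .bridge_call("parse", list(smiles = as.list(todo)))
    for (i in seq_along(todo)) {
      assign(paste0("s:", todo[i]),
             list(valid = isTRUE(val$valid[[i]]),
                  canonical = if (is.null(val$canonical[[i]])) NA_character_
                              else val$canonical[[i]]),
             envir = .bridge$cache_parse)
    }
  }
  hit <- lapply(key, get, envir = .bridge$cache_parse)
  data.frame(smiles = smiles,
             valid = vapply(hit, `[[`, logical(1), "valid"),
             canonical = vapply(hit, `[[`, character(1), "canonical"),
             stringsAsFactors = FALSE)
}

#' Test whether strings are valid SMILES
#'
#' Validity means the string is parseable (and sanitizable) by RDKit,
#' which is the criterion used by every downstream rate in this package.
#' @param smiles Character vector.
#' @return Logical vector.
#' @examples \dontrun{is_valid_smiles(c("CCO", "C("))}
#' @export
is_valid_smiles <- function(smiles) parse_smiles(smiles)$valid

#' Canonicalize SMILES strings
#'
#' @param smiles Character vector of valid SMILES.
#' @return Character vector of RDKit canonical SMILES (`NA` if invalid).
#' @export
canonicalize_smiles <- function(smiles) parse_smiles(smiles)$canonical

#' Compute ECFP6 fingerprints (Morgan, radius 3, hashed)
#'
#' @param smiles Character vector of SMILES.
#' @param nbits Fingerprint length in bits (default 4096).
#' @param radius Morgan radius in bonds (default 3, i.e. ECFP6).
#' @return A list of sorted 0-based on-bit positions, one integer vector
#'   per molecule.
#' @export
compute_ecfp6 <- function(smiles, nbits = 4096L, radius = 3L) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  use_cache <- nbits == 4096L && radius == 3L
  fetch <- function(batch) {
    val <- .bridge_call("ecfp6", list(smiles = as.list(batch),
                                      nbits = nbits, radius = radius))
    lapply(seq_along(batch), function(i) {
      v <- val[[i]]
      if (is.null(v)) stop("invalid SMILES cannot be fingerprinted: ",
                           batch[i], call. = FALSE)
      as.integer(unlist(v))
    })
  }
  if (!use_cache) {
    out <- fetch(smiles)
  } else {
    key <- paste0("s:", smiles)
    known <- vapply(key, exists, logical(1), envir = .bridge$cache_fp,
                    inherits = FALSE)
    miss <- unique(smiles[!known])
    if (length(miss)) {
      got <- fetch(miss)
      for (i in seq_along(miss)) assign(paste0("s:", miss[i]), got[[i]],
                                        envir = .bridge$cache_fp)
    }
    out <- lapply(key, get, envir = .bridge$cache_fp)
  }
  names(out) <- NULL
  out
}

#' Match a SMARTS pattern against molecules
#'
#' @param smiles Character vector; invalid entries match `FALSE`.
#' @param smarts A single SMARTS pattern.
#' @return Logical vector.
#' @export
match_smarts <- function(smiles, smarts) {
  stopifnot(is.character(smiles), is.character(smarts), length(smarts) == 1L)
  vapply(.bridge_call("match_smarts",
                      list(smiles = as.list(smiles), smarts = smarts)),
         isTRUE, logical(1))
}

.bridge_scaffold <- function(smiles, mode) {
  val <- .bridge_call("scaffold", list(smiles = as.list(smiles), mode = mode))
  vapply(val, function(v) if (is.null(v)) NA_character_ else v, character(1))
}
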