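## Internal helpers: external tool invocation, alphabets, small utilities.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' @importFrom tools file_path_sans_ext
NULL

.findTool <- function(name) {
  path <- Sys.which(name)
  if (!nzchar(path)) {
    stop("external tool '", name, "' not found on PATH", call. = FALSE)
  }
  unname(path)
}

## Run an external command, stopping with its stderr on failure.
## `stdout = TRUE` captures output; a path redirects it to that file.
.runTool <- function(name, args, stdout = TRUE) {
  tool <- .findTool(name)
  if (isTRUE(stdout)) {
    out <- suppressWarnings(system2(tool, args, stdout = TRUE,
                                    stderr = TRUE))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0) {
      stop(name, " failed (exit ", status, "): ",
           paste(utils::tail(out, 5), collapse = " | "), call. = FALSE)
    }
    return(invisible(out))
  }
  errFile <- tempfile("stderr")
  on.exit(unlink(errFile))
  status <- suppressWarnings(system2(tool, args, stdout = stdout,
                                     stderr = errFile))
  if (!identical(status, 0L)) {
    err <- if (file.exists(errFile)) readLines(errFile) else character(0)
    stop(name, " failed (exit ", status, "): ",
         paste(utils::tail(err, 5), collapse = " | "), call. = FALSE)
  }
  invisible(NULL)
}

.tmpDir <- function(prefix = "classiphage") {
  d <- tempfile(prefix)
  dir.create(d, recursive = TRUE)
  d
}

## Sanitize sequences to the 20-letter alphabet plus X; strip stop symbols.
.cleanProtein <- function(x) {
  x <- toupper(gsub("\\*", "", x))
  gsub(paste0("[^", paste(.AA20, collapse = ""), "]"), "X", x)
}

## Deterministic sub-seed derivation (kept below 2^31).
.subSeed <- function(seed, k) {
  (as.numeric(seed) * 1000003 + k) %% 2147483647
}

.msg <- function(...) message("[classiphage] ", ...)
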