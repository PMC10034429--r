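#' @title EC label constants
#' @description Sentinel labels used throughout the package: the gap string
#'   used in alignments and the "no EC assigned" sentinel, which is dissimilar
#'   (value 1) to every other label and identical only to itself.
#' @name ec-constants
NULL

#' Gap label used in ESS alignments
#' @export
EC_GAP <- "-.-.-"

#' Sentinel label for enzymes with no EC number assigned
#' @export
EC_UNASSIGNED <- "9.9.9"

#' Default weight factors for EC classification levels 1-3
#'
#' Weights applied to the per-level entropies when combining them into a
#' single dissimilarity; the first classification level dominates.
#' @export
DEFAULT_EC_WEIGHTS <- c(15, 10, 1)

#' Test whether strings are syntactically valid three-level EC labels
#'
#' A valid label is three dot-separated non-negative integers, e.g. "2.7.1".
#' The unassigned sentinel "9.9.9" is valid; the gap "-.-.-" is not.
#'
#' @param x character vector.
#' @return logical vector.
#' @export
is_ec_label <- function(x) {
  grepl("^[0-9]+\\.[0-9]+\\.[0-9]+$", x)
}

#' Parse a colon-separated ESS string into a vector of EC labels
#'
#' The input dialect is the one used on the command line and in one-ESS-per-
#' line text files: three-level EC numbers joined by ":", e.g.
#' `"2.7.1:5.3.1:5.3.1:2.7.1:4.1.2:1.2.1"`.
#'
#' @param x a single character string.
#' @return character vector of EC labels.
#' @export
parse_ess <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop("expected a single ESS string", call. = FALSE)
  }
  labs <- trimws(strsplit(x, ":", fixed = TRUE)[[1L]])
  if (length(labs) == 0L) stop("empty ESS string", call. = FALSE)
  bad <- which(!is_ec_label(labs))
  if (length(bad) > 0L) {
    stop(sprintf("malformed EC label '%s' at position %d", labs[bad[1L]], bad[1L]),
         call. = FALSE)
  }
  labs
}

#' Format a vector of EC labels as a colon-separated ESS string
#' @param labels character vector of EC labels (gaps allowed).
#' @return single character string.
#' @export
format_ess <- function(labels) {
  paste(labels, collapse = ":")
}

#' Three-level prefix of a four-level EC string
#' @param x character vector of four-level EC strings ("2.7.1.1") or the
#'   sentinel "9.9.9".
#' @return character vector of three-level prefixes.
#' @keywords internal
ec3_prefix <- function(x) {
  sub("^([0-9]+\\.[0-9]+\\.[0-9]+)\\.[^.]+$", "\\1", x)
}

# Coerce the accepted ESS representations (colon string, label vector, ess
# object) to a plain label vector.
as_ess_labels <- function(x) {
  if (inherits(x, "ess")) return(x$labels3)
  if (is.character(x) && length(x) == 1L && grepl(":", x, fixed = TRUE)) {
    return(parse_ess(x))
  }
  if (is.character(x)) {
    if (length(x) == 1L && !is_ec_label(x)) {
      stop(sprintf("malformed EC label '%s'", x), call. = FALSE)
    }
    bad <- which(!is_ec_label(x) & x != EC_GAP)
    if (length(bad) > 0L) {
      stop(sprintf("malformed EC label '%s' at position %d", x[bad[1L]], bad[1L]),
           call. = FALSE)
    }
    return(x)
  }
  stop("cannot interpret input as an ESS", call. = FALSE)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
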