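# Consensus secondary-structure notation: bracket parsing and pair tables.

WUSS_OPEN   <- c("<", "(", "[", "{")
WUSS_CLOSE  <- c(">", ")", "]", "}")
WUSS_SINGLE <- c(".", ",", ":", "_", "-", "~")

#' Parse a WUSS-style consensus structure string into a pair table
#'
#' All four bracket types (`<>`, `()`, `[]`, `{}`) denote base pairs and are
#' equivalent; a closing bracket must match the type of the innermost open
#' bracket, which enforces properly nested (pseudoknot-free) structure.
#' The characters `.,:_-~` mark unpaired columns. Letter-coded pseudoknot
#' layers (`Aa`, `Bb`, ...) are accepted but treated as unpaired, with a
#' warning, because all downstream algorithms assume nested structure.
#'
#' @param ss structure string, one character per alignment column.
#' @return a `pair_table` object: list with `length` (number of columns) and
#'   `partner` (integer vector; `partner[i]` is the paired column of `i`, or
#'   0 if column `i` is unpaired).
#' @examples
#' pt <- parse_wuss("<<<___>>>")
#' pt$partner
#' @export
parse_wuss <- function(ss) {
  if (!is.character(ss) || length(ss) != 1L || nchar(ss) == 0L) {
    stop("structure string must be a single non-empty string")
  }
  chars <- strsplit(ss, "", fixed = TRUE)[[1]]
  n <- length(chars)
  partner <- integer(n)
  stack_pos <- integer(0)
  stack_type <- integer(0)
  saw_knot <- FALSE
  for (i in seq_len(n)) {
    ch <- chars[i]
    oi <- match(ch, WUSS_OPEN)
    ci <- match(ch, WUSS_CLOSE)
    if (!is.na(oi)) {
      stack_pos <- c(stack_pos, i)
      stack_type <- c(stack_type, oi)
    } else if (!is.na(ci)) {
      if (length(stack_pos) == 0L) {
        stop("unbalanced structure at column ", i)
      }
      top <- length(stack_pos)
      if (stack_type[top] != ci) {
        stop("mismatched bracket type at column ", i)
      }
      j <- stack_pos[top]
      partner[j] <- i
      partner[i] <- j
      stack_pos <- stack_pos[-top]
      stack_type <- stack_type[-top]
    } else if (ch %in% WUSS_SINGLE) {
      # unpaired
    } else if (grepl("^[A-Za-z]$", ch)) {
      saw_knot <- TRUE
    } else {
      stop("illegal structure character '", ch, "' at column ", i)
    }
  }
  if (length(stack_pos) > 0L) {
    stop("unbalanced structure at column ", stack_pos[1])
  }
  if (saw_knot) {
    warning("pseudoknot layer annotation treated as unpaired")
  }
  structure(list(length = n, partner = partner), class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  np <- sum(x$partner > 0) / 2
  cat("pair_table:", x$length, "columns,", np, "base pairs\n")
  invisible(x)
}

# Render a pair table back to a bracket string (match columns only).
pair_table_to_wuss <- function(pt) {
  out <- rep(":", pt$length)
  paired <- which(pt$partner > 0)
  out[paired[pt$partner[paired] > paired]] <- "<"
  out[paired[pt$partner[paired] < paired]] <- ">"
  paste(out, collapse = "")
}

# Validates nesting/involution; used by property tests and internally after
# restricting a pair table to a column subset.
validate_pair_table <- function(pt) {
  p <- pt$partner
  n <- pt$length
  stopifnot(length(p) == n)
  paired <- which(p > 0)
  if (!all(p[p[paired]] == paired) || any(p[paired] == paired)) {
    stop("partner vector is not an involution")
  }
  for (i in paired) {
    j <- p[i]
    if (i < j) {
      inside <- p[(i + 1):(j - 1)]
      inside <- inside[inside > 0]
      if (any(inside < i | inside > j)) stop("pairs are not nested")
    }
  }
  invisible(TRUE)
}

# Restrict a pair table to a logical column mask: kept columns are
# renumbered; a kept column whose partner is dropped becomes unpaired.
subset_pair_table <- function(pt, keep) {
  stopifnot(length(keep) == pt$length)
  newidx <- cumsum(keep)
  partner <- integer(sum(keep))
  for (i in which(keep)) {
    j <- pt$partner[i]
    partner[newidx[i]] <- if (j > 0 && keep[j]) newidx[j] else 0L
  }
  structure(list(length = sum(keep), partner = partner), class = "pair_table")
}
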