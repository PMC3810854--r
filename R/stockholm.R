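# Stockholm alignment and FASTA database input/output.

#' Construct a structure-annotated alignment
#'
#' The central input object for model building: aligned RNA rows plus a
#' consensus secondary-structure line of the same length.
#'
#' @param names sequence identifiers (unique, non-empty).
#' @param rows aligned strings over `{A,C,G,U,-,.,_,~}` (T is normalized to
#'   U, lowercase raised).
#' @param ss_cons consensus structure string, same length as the rows.
#' @param id optional family name.
#' @return a `structured_alignment` object.
#' @export
structured_alignment <- function(names, rows, ss_cons, id = NULL) {
  rows <- normalize_rna(rows)
  obj <- structure(
    list(names = as.character(names), rows = rows,
         ss_cons = ss_cons, id = id),
    class = "structured_alignment"
  )
  validate_structured_alignment(obj)
  obj
}

validate_structured_alignment <- function(aln) {
  if (length(aln$names) != length(aln$rows)) {
    stop("names and rows differ in length")
  }
  if (anyDuplicated(aln$names)) stop("duplicate sequence identifiers")
  if (any(!nzchar(aln$names))) stop("empty sequence identifier")
  w <- nchar(aln$ss_cons)
  if (w < 1L) stop("alignment must have at least one column")
  if (any(nchar(aln$rows) != w)) {
    bad <- aln$names[nchar(aln$rows) != w][1]
    stop("row length mismatch for sequence '", bad, "'")
  }
  # also checks bracket balance / nesting of the structure line
  parse_wuss(aln$ss_cons)
  invisible(TRUE)
}

#' @export
print.structured_alignment <- function(x, ...) {
  cat("structured_alignment", if (!is.null(x$id)) paste0("'", x$id, "'"),
      ":", length(x$rows), "sequences x", nchar(x$ss_cons), "columns\n")
  invisible(x)
}

#' Read Stockholm alignments
#'
#' Parses one or more `# STOCKHOLM 1.0` blocks. Interleaved records are
#' concatenated per sequence; the `#=GC SS_cons` line is required (models
#' need structure). DNA letters are normalized to RNA.
#'
#' @param path file path.
#' @return a list of [structured_alignment()] objects, one per block.
#' @export
read_stockholm <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!grepl("^# STOCKHOLM", lines[i])) { i <- i + 1L; next }
    i <- i + 1L
    seqs <- list()
    order <- character(0)
    ss <- character(0)
    id <- NULL
    while (i <= n && !grepl("^//", lines[i])) {
      ln <- lines[i]
      i <- i + 1L
      if (grepl("^\\s*$", ln)) next
      if (grepl("^#=GC\\s+SS_cons\\s", ln)) {
        ss <- c(ss, sub("^#=GC\\s+SS_cons\\s+", "", ln))
      } else if (grepl("^#=GF\\s+ID\\s", ln)) {
        id <- sub("^#=GF\\s+ID\\s+", "", ln)
      } else if (grepl("^#", ln)) {
        next  # other annotation ignored
      } else {
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        if (length(parts) != 2L) stop("malformed alignment line: ", ln)
        nm <- parts[1]
        if (is.null(seqs[[nm]])) {
          seqs[[nm]] <- parts[2]
          order <- c(order, nm)
        } else {
          seqs[[nm]] <- paste0(seqs[[nm]], parts[2])
        }
      }
    }
    i <- i + 1L  # past "//"
    if (length(seqs) == 0L) next
    if (length(ss) == 0L) {
      stop("missing #=GC SS_cons line: models require structure annotation")
    }
    out[[length(out) + 1L]] <- structured_alignment(
      names = order,
      rows = unlist(seqs[order], use.names = FALSE),
      ss_cons = paste(ss, collapse = ""),
      id = id
    )
  }
  out
}

#' Write Stockholm alignments
#'
#' @param alns a `structured_alignment` or list of them.
#' @param path output file path.
#' @export
write_stockholm <- function(alns, path) {
  if (inherits(alns, "structured_alignment")) alns <- list(alns)
  con <- file(path, "w")
  on.exit(close(con))
  for (aln in alns) {
    validate_structured_alignment(aln)
    writeLines("# STOCKHOLM 1.0", con)
    if (!is.null(aln$id)) writeLines(paste("#=GF ID", aln$id), con)
    wname <- max(nchar(aln$names), nchar("#=GC SS_cons")) + 2L
    for (k in seq_along(aln$names)) {
      writeLines(sprintf("%-*s%s", wname, aln$names[k], aln$rows[k]), con)
    }
    writeLines(sprintf("%-*s%s", wname, "#=GC SS_cons", aln$ss_cons), con)
    writeLines("//", con)
  }
  invisible(path)
}

#' Open a streaming FASTA reader
#'
#' Returns an iterator over records so that large target databases need not
#' be held in memory at once. Records are normalized to uppercase RNA.
#'
#' @param path FASTA file.
#' @param chunk_size records fetched per underlying read.
#' @return a function; each call returns `list(name=, seq=)` or `NULL` at
#'   end of file.
#' @export
read_fasta <- function(path, chunk_size = 100L) {
  if (!file.exists(path)) stop("no such file: ", path)
  skip <- 0L
  buf <- list()
  pos <- 0L
  seen <- character(0)
  function() {
    pos <<- pos + 1L
    if (pos > length(buf)) {
      recs <- Biostrings::readBStringSet(path, nrec = chunk_size, skip = skip)
      skip <<- skip + length(recs)
      if (length(recs) == 0L) return(NULL)
      nms <- sub("\\s.*$", "", names(recs))
      buf <<- lapply(seq_along(recs), function(k) {
        list(name = nms[k], seq = normalize_rna(as.character(recs[[k]])))
      })
      pos <<- 1L
    }
    rec <- buf[[pos]]
    if (rec$name %in% seen) stop("duplicate identifier: ", rec$name)
    seen <<- c(seen, rec$name)
    rec
  }
}

#' Read an entire FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of RNA sequences.
#' @export
read_fasta_all <- function(path) {
  it <- read_fasta(path)
  out <- character(0)
  nms <- character(0)
  while (!is.null(rec <- it())) {
    out <- c(out, rec$seq)
    nms <- c(nms, rec$name)
  }
  names(out) <- nms
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (anyDuplicated(names(seqs))) stop("duplicate identifiers")
  set <- Biostrings::BStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}
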