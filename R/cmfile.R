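# Plain-text covariance-model file format.
#
# Layout: a header (format version, name, consensus length, null
# frequencies, consensus structure), one NODE line per guide-tree node,
# one STATE line per state (children, transition and emission scores in
# bits, 5 decimals — the model's native precision), optional CAL lines
# (one per calibrated scorer), and a "//" terminator. Multiple models per
# file are allowed.

CM_FORMAT_VERSION <- "COVMOD 1"

fmt_na <- function(x) ifelse(is.na(x), "-", as.character(x))
parse_na_int <- function(x) ifelse(x == "-", NA_integer_, as.integer(x))

#' Write covariance models to a text file
#'
#' @param models a `covariance_model` or list of them.
#' @param path output path.
#' @export
write_cm <- function(models, path) {
  if (inherits(models, "covariance_model")) models <- list(models)
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in models) {
    writeLines(CM_FORMAT_VERSION, con)
    writeLines(paste("NAME", cm$name), con)
    writeLines(paste("CLEN", cm$clen), con)
    writeLines(paste("NULL", paste(sprintf("%.17g", cm$null),
                                   collapse = " ")), con)
    writeLines(paste("SSCONS", cm$cons_ss), con)
    writeLines(paste("NODES", length(cm$nodes)), con)
    for (ni in seq_along(cm$nodes)) {
      nd <- cm$nodes[[ni]]
      writeLines(paste("NODE", ni, nd$type, fmt_na(nd$left),
                       fmt_na(nd$right), fmt_na(nd$parent),
                       paste(nd$children, collapse = ",")), con)
    }
    writeLines(paste("STATES", length(cm$states)), con)
    for (si in seq_along(cm$states)) {
      s <- cm$states[[si]]
      writeLines(paste("STATE", si, s$type, s$node,
                       paste(s$children, collapse = ",") ,
                       paste(sprintf("%.5f", s$tsc), collapse = ","),
                       paste(sprintf("%.5f", s$esc), collapse = ",")), con)
    }
    for (key in names(cm$calibration)) {
      g <- cm$calibration[[key]]
      writeLines(paste("CAL", key, sprintf("%.17g", g$mu),
                       sprintf("%.17g", g$lambda), fmt_na(g$calib_len),
                       fmt_na(g$calib_n), fmt_na(g$seed)), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

split_csv_num <- function(x) {
  if (x == "") numeric(0) else as.numeric(strsplit(x, ",", fixed = TRUE)[[1]])
}
split_csv_int <- function(x) {
  if (x == "") integer(0) else as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
}

#' Read covariance models from a text file
#'
#' @param path model file written by [write_cm()].
#' @return list of `covariance_model` objects (order preserved).
#' @export
read_cm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  models <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (lines[i] != CM_FORMAT_VERSION) {
      stop("unsupported model file version: '", lines[i], "'")
    }
    i <- i + 1L
    hdr <- list()
    nodes <- list()
    states <- list()
    calibration <- list()
    terminated <- FALSE
    while (i <= n) {
      ln <- lines[i]
      i <- i + 1L
      if (ln == "//") { terminated <- TRUE; break }
      parts <- strsplit(ln, " ", fixed = TRUE)[[1]]
      key <- parts[1]
      if (key == "NAME") hdr$name <- sub("^NAME ", "", ln)
      else if (key == "CLEN") hdr$clen <- as.integer(parts[2])
      else if (key == "NULL") hdr$null <- as.numeric(parts[-1])
      else if (key == "SSCONS") hdr$cons_ss <- parts[2]
      else if (key == "NODES") hdr$n_nodes <- as.integer(parts[2])
      else if (key == "STATES") hdr$n_states <- as.integer(parts[2])
      else if (key == "NODE") {
        nodes[[as.integer(parts[2])]] <- list(
          type = parts[3], left = parse_na_int(parts[4]),
          right = parse_na_int(parts[5]), parent = parse_na_int(parts[6]),
          children = split_csv_int(if (length(parts) >= 7) parts[7] else ""))
        nodes[[as.integer(parts[2])]] <-
          nodes[[as.integer(parts[2])]][c("type", "left", "right",
                                          "children", "parent")]
      } else if (key == "STATE") {
        states[[as.integer(parts[2])]] <- list(
          type = parts[3], node = as.integer(parts[4]),
          children = split_csv_int(parts[5]),
          tsc = split_csv_num(parts[6]),
          esc = split_csv_num(if (length(parts) >= 7) parts[7] else ""))
      } else if (key == "CAL") {
        calibration[[parts[2]]] <- gumbel_params(
          mu = as.numeric(parts[3]), lambda = as.numeric(parts[4]),
          calib_len = ifelse(parts[5] == "-", NA_real_,
                             as.numeric(parts[5])),
          calib_n = parse_na_int(parts[6]), seed = parse_na_int(parts[7]))
      } else {
        stop("unrecognized model file line: ", ln)
      }
    }
    if (!terminated) stop("truncated model file (missing '//')")
    if (length(nodes) != hdr$n_nodes || length(states) != hdr$n_states) {
      stop("truncated model file: node/state count mismatch")
    }
    node_states <- vector("list", length(nodes))
    for (si in seq_along(states)) {
      ni <- states[[si]]$node
      node_states[[ni]] <- c(node_states[[ni]], si)
    }
    models[[length(models) + 1L]] <- structure(
      list(name = hdr$name, clen = hdr$clen, nodes = nodes,
           node_states = node_states, states = states, null = hdr$null,
           cons_ss = hdr$cons_ss, calibration = calibration),
      class = "covariance_model")
  }
  if (length(models) == 0L) stop("no models in file")
  models
}
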