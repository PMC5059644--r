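#' Plain-text artifact formats
#'
#' Everything the tool writes is plain text for inspectability: recordings
#' as CSV (one row per sample, columns CH1..CH6) with a JSON metadata
#' sidecar and a label TSV; model sets as versioned JSON; protocols as TSV;
#' language models as ARPA.  Every writer stamps the package version and,
#' where known, the generating seed into the metadata.
#'
#' @name cli_io
NULL

tool_version <- function() {
  as.character(utils::packageVersion("eogdeco"))
}

#' Write a recording to disk
#'
#' Writes `<stem>.csv` (samples), `<stem>.labels.tsv` (start, end, motion;
#' 0-based half-open sample intervals), and `<stem>.json` (sample rate and
#' provenance metadata).
#'
#' @param rec An `eog_recording`.
#' @param stem Output path without extension.
#' @param meta Optional named list merged into the JSON metadata (e.g.
#'   `seed`, profile settings).
#' @return The stem, invisibly.
#' @export
write_recording <- function(rec, stem, meta = list()) {
  stopifnot(inherits(rec, "eog_recording"))
  df <- as.data.frame(rec$samples)
  names(df) <- paste0("CH", seq_len(ncol(df)))
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  utils::write.table(rec$labels, paste0(stem, ".labels.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  info <- c(list(sample_rate = rec$sample_rate, n_samples = nrow(df),
                 n_channels = ncol(df), tool_version = tool_version()),
            meta)
  jsonlite::write_json(info, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' Read a recording written by [write_recording()]
#' @param stem Path stem (without extension).
#' @return An `eog_recording`.
#' @export
read_recording <- function(stem) {
  csv <- paste0(stem, ".csv")
  if (!file.exists(csv)) stop("recording file not found: ", csv)
  df <- utils::read.csv(csv)
  if (!all(paste0("CH", 1:6) %in% names(df)))
    stop("recording CSV must have columns CH1..CH6: ", csv)
  meta_path <- paste0(stem, ".json")
  sample_rate <- 100
  if (file.exists(meta_path)) {
    info <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(info$sample_rate)) sample_rate <- info$sample_rate
    if (!is.null(info$n_samples) && info$n_samples != nrow(df))
      stop("recording CSV is truncated: expected ", info$n_samples,
           " samples, found ", nrow(df))
  }
  labels <- NULL
  lab_path <- paste0(stem, ".labels.tsv")
  if (file.exists(lab_path)) {
    labels <- utils::read.delim(lab_path, stringsAsFactors = FALSE)
    if (!all(c("start", "end", "motion") %in% names(labels)))
      stop("label TSV must have columns start, end, motion: ", lab_path)
  }
  structure(
    list(samples = as.matrix(df[paste0("CH", 1:6)]),
         sample_rate = sample_rate, labels = labels),
    class = "eog_recording"
  )
}

# --- model set JSON ------------------------------------------------------

tying_to_json <- function(ty) {
  node_to_json <- function(node) {
    if (isTRUE(node$leaf)) {
      list(leaf = TRUE, pdf = node$pdf, occ = node$stats$occ)
    } else {
      list(leaf = FALSE, question = node$question, gain = node$gain,
           yes = node_to_json(node$yes), no = node_to_json(node$no))
    }
  }
  list(
    questions = ty$questions,
    n_states = ty$n_states,
    threshold = ty$threshold,
    trees = lapply(ty$trees, node_to_json),
    trans_by_target = lapply(ty$trans_by_target, function(m)
      as.list(as.data.frame(m)))
  )
}

tying_from_json <- function(j) {
  node_from_json <- function(node) {
    if (isTRUE(node$leaf)) {
      list(leaf = TRUE, pdf = as.integer(node$pdf),
           stats = list(occ = node$occ))
    } else {
      list(leaf = FALSE, question = as.integer(node$question),
           gain = node$gain,
           yes = node_from_json(node$yes), no = node_from_json(node$no))
    }
  }
  structure(
    list(
      trees = lapply(j$trees, node_from_json),
      questions = lapply(j$questions, function(q)
        list(name = q$name, side = q$side, motions = unlist(q$motions))),
      n_states = as.integer(j$n_states),
      threshold = j$threshold,
      trans_by_target = lapply(j$trans_by_target, function(cols)
        do.call(cbind, lapply(cols, unlist)))
    ),
    class = "eog_tying"
  )
}

#' Write a model set to JSON
#'
#' Versioned schema holding the unit table (pdf ids and transition rows),
#' the pdf list (mixture weights, means, diagonal variances), the variance
#' floor, optional tying trees, and metadata.
#'
#' @param set An `eog_hmm_set`.
#' @param path Output path.
#' @param meta Extra named metadata (e.g. seed).
#' @export
write_model_set <- function(set, path, meta = list()) {
  stopifnot(inherits(set, "eog_hmm_set"))
  obj <- list(
    schema = "eogdeco-hmm-set/1",
    tool_version = tool_version(),
    dim = set$dim, n_states = set$n_states, var_floor = set$var_floor,
    units = lapply(set$units, function(u) list(
      pdf_ids = u$pdf_ids,
      trans = as.list(as.data.frame(u$trans)))),
    pdfs = lapply(set$pdfs, function(p) list(
      weights = p$weights,
      means = as.list(as.data.frame(p$means)),
      vars = as.list(as.data.frame(p$vars)))),
    meta = c(set$meta, meta)
  )
  if (!is.null(set$tying)) obj$tying <- tying_to_json(set$tying)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model set written by [write_model_set()]
#' @param path JSON path.
#' @return An `eog_hmm_set`.
#' @export
read_model_set <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(j$schema, "eogdeco-hmm-set/1"))
    stop("unsupported model schema: ", j$schema)
  cols_to_matrix <- function(cols)
    do.call(cbind, lapply(cols, function(col) unlist(col)))
  set <- structure(
    list(
      units = lapply(j$units, function(u) list(
        pdf_ids = as.integer(unlist(u$pdf_ids)),
        trans = unname(cols_to_matrix(u$trans)))),
      pdfs = lapply(j$pdfs, function(p) list(
        weights = as.numeric(unlist(p$weights)),
        means = unname(cols_to_matrix(p$means)),
        vars = unname(cols_to_matrix(p$vars)))),
      dim = as.integer(j$dim),
      n_states = as.integer(j$n_states),
      var_floor = as.numeric(unlist(j$var_floor)),
      meta = j$meta
    ),
    class = "eog_hmm_set"
  )
  if (!is.null(j$tying)) {
    set$tying <- tying_from_json(j$tying)
    set$tying$trans_by_target <- lapply(set$tying$trans_by_target, unname)
  }
  set
}

#' Round-trip checks for the text formats
#'
#' Writes the object to a temporary location, reads it back, and verifies
#' equality (within 1e-9 for floating-point content).  Supported:
#' `eog_recording`, `eog_protocol`, `eog_hmm_set`, `char_ngram`.
#'
#' @param x The object to check.
#' @return `TRUE` invisibly if the round trip is faithful; otherwise an
#'   error describing the first mismatch.
#' @export
roundtrip_check <- function(x) {
  tmp <- tempfile("roundtrip_")
  on.exit(unlink(paste0(tmp, "*"), expand = TRUE), add = TRUE)
  near <- function(a, b, what) {
    if (length(a) != length(b) || any(abs(a - b) > 1e-9))
      stop("round-trip mismatch in ", what)
  }
  if (inherits(x, "eog_recording")) {
    write_recording(x, tmp)
    y <- read_recording(tmp)
    near(x$samples, y$samples, "samples")
    near(x$sample_rate, y$sample_rate, "sample_rate")
    if (!is.null(x$labels) &&
        !identical(as.data.frame(x$labels)$motion, y$labels$motion))
      stop("round-trip mismatch in labels")
  } else if (inherits(x, "eog_protocol")) {
    p <- paste0(tmp, ".tsv")
    write_protocol(x, p)
    y <- read_protocol(p)
    if (!identical(x$table[order(names(x$table))],
                   y$table[order(names(y$table))]))
      stop("round-trip mismatch in protocol table")
  } else if (inherits(x, "eog_hmm_set")) {
    p <- paste0(tmp, ".json")
    write_model_set(x, p)
    y <- read_model_set(p)
    for (u in names(x$units)) {
      near(x$units[[u]]$trans, y$units[[u]]$trans, paste0("trans ", u))
      if (!identical(x$units[[u]]$pdf_ids,
                     as.integer(y$units[[u]]$pdf_ids)))
        stop("round-trip mismatch in pdf ids of ", u)
    }
    for (i in seq_along(x$pdfs)) {
      near(x$pdfs[[i]]$weights, y$pdfs[[i]]$weights, "weights")
      near(x$pdfs[[i]]$means, y$pdfs[[i]]$means, "means")
      near(x$pdfs[[i]]$vars, y$pdfs[[i]]$vars, "vars")
    }
  } else if (inherits(x, "char_ngram")) {
    p <- paste0(tmp, ".arpa")
    write_arpa(x, p)
    y <- read_arpa(p, smoothing = x$smoothing,
                   include_end = x$include_end)
    for (k in seq_len(x$order)) {
      keys <- names(x$logp[[k]])
      yk <- unlist(y$logp[[k]][keys])
      near(unlist(x$logp[[k]][keys]), yk, paste0(k, "-gram probabilities"))
    }
  } else {
    stop("roundtrip_check does not support objects of class ",
         paste(class(x), collapse = "/"))
  }
  invisible(TRUE)
}
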