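#' Encode and decode discrete events as integer item codes
#'
#' An event is a (state, probe) pair coded as a single integer: the
#' leading digit is the state (1 = downregulation, 2 = upregulation) and
#' the remaining `width` digits are the probe index, i.e.
#' `code = state * 10^width + probe_index`. With the default width 4 up to
#' 10,000 probes (indices 0..9999) are representable. No-change events
#' (state 0) are never emitted as items.
#'
#' @param state integer vector of states in \{1, 2\}.
#' @param probe_index non-negative integer vector, `< 10^width`.
#' @param code integer vector of item codes.
#' @param width number of digits reserved for the probe index.
#' @return `encode_item()`: integer codes. `decode_item()`: data.frame
#'   with columns `state`, `probe_index`.
#' @export
encode_item <- function(state, probe_index, width = 4L) {
  state <- as.integer(state); probe_index <- as.integer(probe_index)
  if (any(!state %in% c(1L, 2L))) stop("item state must be 1 or 2")
  if (any(probe_index < 0L)) stop("probe index must be non-negative")
  if (any(probe_index >= 10^width))
    stop("probe index overflows width ", width)
  state * as.integer(10^width) + probe_index
}

#' @rdname encode_item
#' @export
decode_item <- function(code, width = 4L) {
  code <- as.integer(code)
  base <- as.integer(10^width)
  state <- code %/% base
  if (any(!state %in% c(1L, 2L))) stop("invalid item code(s)")
  data.frame(state = state, probe_index = code %% base)
}

#' Build the probe codebook for item encoding
#'
#' Probe indices are assigned once per run by a stable lexicographic sort
#' of the probe ids (0-based), so item codes are reproducible across
#' stages and runs. The width auto-widens with a warning when the probe
#' count exceeds `10^width`.
#'
#' @param probes data.frame with columns `probe_id`, `gene_symbol`.
#' @param width digits reserved for the probe index (default 4).
#' @return a `Codebook` data.frame: `probe_index`, `probe_id`,
#'   `gene_symbol`, with attribute `width`.
#' @export
make_codebook <- function(probes, width = 4L) {
  probes <- probes[order(probes$probe_id), , drop = FALSE]
  if (nrow(probes) > 10^width) {
    width <- ceiling(log10(nrow(probes)))
    warning("probe count exceeds code width; widening to ", width, " digits")
  }
  cb <- data.frame(probe_index = seq_len(nrow(probes)) - 1L,
                   probe_id = probes$probe_id,
                   gene_symbol = normalize_gene_symbol(probes$gene_symbol),
                   stringsAsFactors = FALSE)
  attr(cb, "width") <- as.integer(width)
  class(cb) <- c("Codebook", "data.frame")
  cb
}

#' Human-readable label for item codes
#'
#' Renders codes as `probe/GENE=state`, the notation used in rule tables.
#'
#' @param code integer item codes.
#' @param codebook a `Codebook`.
#' @return character vector of labels.
#' @export
item_label <- function(code, codebook) {
  if (!length(code)) return(character(0))
  d <- decode_item(code, attr(codebook, "width"))
  i <- match(d$probe_index, codebook$probe_index)
  if (anyNA(i)) stop("item code(s) not in codebook")
  paste0(codebook$probe_id[i], "/", codebook$gene_symbol[i], "=", d$state)
}

#' Genes and states for item codes
#' @inheritParams item_label
#' @return data.frame with `probe_id`, `gene`, `state` per code.
#' @export
item_genes <- function(code, codebook) {
  d <- decode_item(code, attr(codebook, "width"))
  i <- match(d$probe_index, codebook$probe_index)
  if (anyNA(i)) stop("item code(s) not in codebook")
  data.frame(probe_id = codebook$probe_id[i],
             gene = codebook$gene_symbol[i], state = d$state,
             stringsAsFactors = FALSE)
}

#' Write / read the item codebook sidecar
#'
#' One row per (state, probe) code: columns `code, probe_id, gene`.
#'
#' @param codebook a `Codebook`.
#' @param path TSV path.
#' @export
write_codebook <- function(codebook, path) {
  w <- attr(codebook, "width")
  df <- rbind(
    data.frame(code = encode_item(1L, codebook$probe_index, w),
               probe_id = codebook$probe_id, gene = codebook$gene_symbol),
    data.frame(code = encode_item(2L, codebook$probe_index, w),
               probe_id = codebook$probe_id, gene = codebook$gene_symbol))
  df <- df[order(df$code), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("integer", "character", "character"))
  w <- max(nchar(as.character(df$code))) - 1L
  d <- decode_item(df$code, w)
  cb <- unique(data.frame(probe_index = d$probe_index,
                          probe_id = df$probe_id,
                          gene_symbol = normalize_gene_symbol(df$gene),
                          stringsAsFactors = FALSE))
  cb <- cb[order(cb$probe_index), , drop = FALSE]
  rownames(cb) <- NULL
  attr(cb, "width") <- w
  class(cb) <- c("Codebook", "data.frame")
  cb
}

#' Construct a sequence database
#'
#' @param sequences list (one element per subject) of lists of integer
#'   item-code vectors (one itemset per mining interval; empty itemsets
#'   allowed and kept, they preserve ordinal positions).
#' @param group group label.
#' @param codebook a `Codebook` (optional but required for labels).
#' @param subjects optional subject ids (names the sequences).
#' @return a `SequenceDatabase`.
#' @export
sequence_database <- function(sequences, group = NA_character_,
                              codebook = NULL, subjects = NULL) {
  sequences <- lapply(sequences, function(s)
    lapply(s, function(it) sort(unique(as.integer(it)))))
  if (!is.null(subjects)) names(sequences) <- subjects
  structure(list(sequences = sequences, group = group, codebook = codebook),
            class = "SequenceDatabase")
}

#' @export
print.SequenceDatabase <- function(x, ...) {
  cat(sprintf("SequenceDatabase [%s]: |SD| = %d sequences, %d distinct items\n",
              x$group, length(x$sequences),
              length(unique(unlist(x$sequences)))))
  invisible(x)
}

#' Number of sequences in a database
#' @param seqdb a `SequenceDatabase`.
#' @return integer |SD|.
#' @export
n_sequences <- function(seqdb) length(seqdb$sequences)

#' Build a per-group sequence database from discrete states
#'
#' One sequence per subject; itemset k holds the encoded nonzero events of
#' mining interval k. Subjects whose states are all zero contribute a
#' sequence of empty itemsets and still count in |SD| (they enter every
#' support denominator).
#'
#' @param discrete a `DiscreteMatrix` from [discretize()].
#' @param intervals an `IntervalSet`; only mining intervals are used.
#' @param group group label (must match the discrete matrix).
#' @param codebook a `Codebook` covering the probes.
#' @return a `SequenceDatabase`.
#' @export
build_sequence_db <- function(discrete, intervals, group, codebook) {
  stopifnot(inherits(discrete, "DiscreteMatrix"))
  if (!identical(attr(discrete, "group"), group))
    stop("group absent from discrete matrix: ", group)
  ivs <- mining_intervals(intervals)$label
  if (!all(ivs %in% dimnames(discrete)[[3L]]))
    stop("mining interval(s) missing from discrete matrix")
  subj <- attr(discrete, "subjects")
  probes <- attr(discrete, "probes")
  pidx <- codebook$probe_index[match(probes$probe_id, codebook$probe_id)]
  if (anyNA(pidx)) stop("probe(s) missing from codebook")
  w <- attr(codebook, "width")
  sequences <- lapply(seq_along(subj), function(j) {
    lapply(ivs, function(iv) {
      s <- discrete[, j, iv]
      nz <- which(s != 0L)
      if (!length(nz)) return(integer(0))
      sort(encode_item(s[nz], pidx[nz], w))
    })
  })
  sequence_database(sequences, group = group, codebook = codebook,
                    subjects = subj)
}

#' Write / read a sequence database in SPMF text format
#'
#' One line per sequence: items are space-separated within an itemset,
#' `-1` ends an itemset and `-2` ends the sequence. An empty itemset is a
#' bare `-1`, preserving ordinal positions. A line without a final `-2`,
#' or any non-integer token, is a parse error.
#'
#' @param seqdb a `SequenceDatabase`.
#' @param path file path.
#' @param group,codebook optional metadata re-attached on read.
#' @export
write_spmf <- function(seqdb, path) {
  lines <- vapply(seqdb$sequences, function(s) {
    paste(c(unlist(lapply(s, function(it) c(it, -1L))), -2L), collapse = " ")
  }, character(1))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_spmf
#' @export
read_spmf <- function(path, group = NA_character_, codebook = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sequences <- lapply(lines, function(ln) {
    toks <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (!all(grepl("^-?[0-9]+$", toks)))
      stop("non-integer token in SPMF file: ", ln)
    v <- as.integer(toks)
    if (v[length(v)] != -2L) stop("SPMF sequence missing terminal -2: ", ln)
    v <- v[-length(v)]
    if (length(v) && v[length(v)] != -1L)
      stop("SPMF itemset missing terminal -1: ", ln)
    breaks <- which(v == -1L)
    out <- list()
    start <- 1L
    for (b in breaks) {
      out[[length(out) + 1L]] <-
        if (b > start) v[start:(b - 1L)] else integer(0)
      start <- b + 1L
    }
    out
  })
  sequence_database(sequences, group = group, codebook = codebook)
}
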