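# Proteome container and all external file formats (FASTA, TSV behavior
# profiles, interval annotations, term maps, known-motif catalogs, outputs).
#
# Coordinate convention: 0-based, half-open everywhere (instance starts,
# domain and disorder intervals). TSV dialect: tab-separated, UTF-8, lines
# starting with '#' ignored.

#' Construct a proteome from named sequences
#'
#' A proteome is an ordered, named set of amino-acid sequences; the entry
#' order is stable and defines the row order of every downstream profile.
#' Sequences are uppercased. Non-canonical residues (X, U, B, Z, `*`) are
#' retained but are never matched by any motif position, wildcard included.
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @return A `slim_proteome` (named character vector).
#' @export
#' @examples
#' proteome(c(A = "MSPARK", B = "KKRK"))
proteome <- function(sequences) {
  ids <- names(sequences)
  if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
    stop("every protein needs a non-empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(sequences))
  if (any(!nzchar(seqs)))
    stop("empty sequence for id(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  bad <- grepl("[^A-Z*]", seqs)
  if (any(bad))
    stop("non-letter characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  names(seqs) <- ids
  structure(seqs, class = "slim_proteome")
}

#' @export
print.slim_proteome <- function(x, ...) {
  cat("<slim_proteome> ", length(x), " proteins, total ",
      sum(nchar(x)), " residues\n", sep = "")
  invisible(x)
}

#' @export
`[.slim_proteome` <- function(x, i) {
  structure(NextMethod(), class = "slim_proteome")
}

#' Read a proteome from a FASTA file
#'
#' The id of each record is the header token up to the first whitespace.
#' Sequences are uppercased on read. Duplicate ids, empty records, and
#' non-letter characters (other than `*`, which is retained as a
#' non-canonical residue) are hard errors.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A [proteome()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("non-letter characters in FASTA file: ", path, call. = FALSE)
      invokeRestart("muffleWarning")
    })
  ids <- sub("\\s.*$", "", names(set))
  if (any(Biostrings::width(set) == 0)) {
    empty <- ids[Biostrings::width(set) == 0]
    stop("empty FASTA record(s): ", paste(empty, collapse = ", "))
  }
  seqs <- as.character(set)
  names(seqs) <- ids
  proteome(seqs)
}

#' Write a proteome to FASTA
#'
#' @param x A [proteome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  set <- Biostrings::AAStringSet(unclass(x))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

read_tsv_raw <- function(path, n_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "#", colClasses = "character",
                          stringsAsFactors = FALSE, blank.lines.skip = TRUE)
  if (ncol(df) < n_cols)
    stop("expected at least ", n_cols, " tab-separated columns in ", path)
  df
}

#' Construct a behavior profile from discrete labels
#'
#' The behavior profile assigns each protein a class index in `0..C-1`.
#' Distinct labels are mapped to indices in order of first appearance.
#' Profile row order follows proteome entry order. Proteins present in the
#' proteome but absent from `ids` are excluded from the analysis universe
#' (they are not a background class).
#'
#' @param ids Protein ids (must all be in `prot`).
#' @param labels Class labels aligned with `ids`.
#' @param prot A [proteome()].
#' @return A `slim_behavior` with fields `ids`, `class` (integer, 0-based),
#'   `labels` (class label per index), `source`.
#' @export
behavior_discrete <- function(ids, labels, prot) {
  stopifnot(length(ids) == length(labels))
  check_behavior_ids(ids, prot)
  lv <- unique(labels)
  cls <- match(labels, lv) - 1L
  ord <- order(match(ids, names(prot)))
  bp <- structure(list(ids = ids[ord], class = cls[ord],
                       labels = as.character(lv),
                       source = list(type = "discrete")),
                  class = "slim_behavior")
  validate_behavior(bp)
}

#' Construct a behavior profile by equal-population binning of values
#'
#' Quantitative measurements are discretized with [discretize_equal()] into
#' `n_bins` equally populated classes (maximum-entropy discretization); class
#' 0 holds the smallest values.
#'
#' @param ids Protein ids (must all be in `prot`).
#' @param values Finite numeric values aligned with `ids`.
#' @param n_bins Number of bins (default 10).
#' @param prot A [proteome()].
#' @return A `slim_behavior` with `source$type == "quantized"`.
#' @export
behavior_quantize <- function(ids, values, n_bins = 10L, prot) {
  stopifnot(length(ids) == length(values))
  check_behavior_ids(ids, prot)
  if (n_bins > length(ids))
    stop("n_bins (", n_bins, ") exceeds number of proteins (", length(ids), ")")
  cls <- discretize_equal(values, n_bins)
  ord <- order(match(ids, names(prot)))
  edges <- tapply(values, cls, range)
  bp <- structure(list(ids = ids[ord], class = cls[ord],
                       labels = paste0("bin", seq_len(n_bins) - 1L),
                       source = list(type = "quantized", n_bins = n_bins,
                                     bin_ranges = edges)),
                  class = "slim_behavior")
  validate_behavior(bp)
}

check_behavior_ids <- function(ids, prot) {
  if (anyDuplicated(ids))
    stop("duplicate protein id(s) in behavior data: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  missing <- setdiff(ids, names(prot))
  if (length(missing))
    stop("behavior id(s) not in proteome: ",
         paste(utils::head(missing, 5), collapse = ", "))
  invisible(TRUE)
}

validate_behavior <- function(bp) {
  C <- length(bp$labels)
  if (C < 2) stop("behavior profile needs at least 2 classes, got ", C)
  sizes <- tabulate(bp$class + 1L, C)
  if (any(sizes == 0))
    stop("empty behavior class(es): ",
         paste(bp$labels[sizes == 0], collapse = ", "))
  bp
}

#' @export
print.slim_behavior <- function(x, ...) {
  cat("<slim_behavior> ", length(x$ids), " proteins, ",
      length(x$labels), " classes (", x$source$type, ")\n", sep = "")
  print(stats::setNames(tabulate(x$class + 1L, length(x$labels)), x$labels))
  invisible(x)
}

#' Read a behavior profile from a two-column TSV
#'
#' Columns are (protein id, value). In `discrete` mode distinct labels become
#' class indices in first-appearance order; in `quantitative` mode values are
#' parsed as finite reals and split into `n_bins` equally populated classes.
#' Ids absent from the proteome are dropped with a message reporting the
#' count.
#'
#' @param path TSV path ('#' comment lines ignored).
#' @param prot A [proteome()].
#' @param mode `"discrete"` or `"quantitative"`.
#' @param n_bins Bins for quantitative mode (default 10).
#' @return A `slim_behavior`.
#' @export
read_behavior <- function(path, prot, mode = c("discrete", "quantitative"),
                          n_bins = 10L) {
  mode <- match.arg(mode)
  df <- read_tsv_raw(path, 2L)
  ids <- df[[1]]
  vals <- df[[2]]
  keep <- ids %in% names(prot)
  if (any(!keep))
    message("read_behavior: dropped ", sum(!keep),
            " id(s) not present in the proteome")
  ids <- ids[keep]
  vals <- vals[keep]
  if (length(ids) == 0) stop("no behavior ids overlap the proteome")
  if (mode == "discrete") {
    if (length(unique(vals)) < 2)
      stop("fewer than 2 distinct classes after filtering")
    behavior_discrete(ids, vals, prot)
  } else {
    num <- suppressWarnings(as.numeric(vals))
    if (any(!is.finite(num)))
      stop("non-finite quantitative value(s), first at line with id ",
           ids[which(!is.finite(num))[1]])
    behavior_quantize(ids, num, n_bins, prot)
  }
}

#' Write a behavior profile to TSV
#'
#' Discrete profiles round-trip exactly through [read_behavior()].
#'
#' @param bp A `slim_behavior`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_behavior <- function(bp, path) {
  df <- data.frame(id = bp$ids, label = bp$labels[bp$class + 1L])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read domain or disorder intervals from TSV
#'
#' Rows are `(protein_id, name, start, end)` with 0-based half-open
#' coordinates; for disorder the name column may be blank and overlapping
#' intervals are merged per protein. Out-of-bounds intervals are hard errors.
#'
#' @param path TSV path.
#' @param prot A [proteome()].
#' @param kind `"domain"` or `"disorder"`.
#' @return A `slim_domains` or `slim_disorder` data frame with columns
#'   `protein_id`, `name` (domains only), `start`, `end`.
#' @export
read_intervals <- function(path, prot, kind = c("domain", "disorder")) {
  kind <- match.arg(kind)
  df <- read_tsv_raw(path, 4L)
  out <- data.frame(protein_id = df[[1]], name = df[[2]],
                    start = suppressWarnings(as.integer(df[[3]])),
                    end = suppressWarnings(as.integer(df[[4]])),
                    stringsAsFactors = FALSE)
  if (kind == "domain") domain_annotations(out, prot)
  else disorder_mask(out[c("protein_id", "start", "end")], prot)
}

validate_intervals <- function(df, prot, what) {
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("non-integer interval bounds in ", what, " annotations")
  missing <- setdiff(df$protein_id, names(prot))
  if (length(missing))
    stop(what, " annotation for unknown protein(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  len <- nchar(unclass(prot))[df$protein_id]
  bad <- df$start < 0 | df$start >= df$end | df$end > len
  if (any(bad)) {
    i <- which(bad)[1]
    stop("out-of-bounds ", what, " interval for ", df$protein_id[i],
         ": [", df$start[i], ", ", df$end[i], ") on length ", len[i])
  }
  invisible(TRUE)
}

#' Construct domain annotations
#'
#' @param df Data frame with columns `protein_id`, `name`, `start`, `end`
#'   (0-based half-open). Intervals may overlap.
#' @param prot A [proteome()].
#' @return A `slim_domains` data frame.
#' @export
domain_annotations <- function(df, prot) {
  if (any(!nzchar(df$name))) stop("empty domain name(s)")
  validate_intervals(df, prot, "domain")
  structure(df[c("protein_id", "name", "start", "end")],
            class = c("slim_domains", "data.frame"))
}

#' Construct a disorder mask (intervals merged per protein)
#'
#' @param df Data frame with columns `protein_id`, `start`, `end` (0-based
#'   half-open). Overlapping or touching intervals are merged on load.
#' @param prot A [proteome()].
#' @return A `slim_disorder` data frame with non-overlapping intervals.
#' @export
disorder_mask <- function(df, prot) {
  validate_intervals(df, prot, "disorder")
  pieces <- lapply(split(df, df$protein_id), function(d) {
    d <- d[order(d$start, d$end), ]
    s <- d$start; e <- d$end
    ms <- s[1]; me <- e[1]; out_s <- integer(0); out_e <- integer(0)
    if (nrow(d) > 1) {
      for (i in 2:nrow(d)) {
        if (s[i] <= me) me <- max(me, e[i])
        else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s[i]; me <- e[i] }
      }
    }
    data.frame(protein_id = d$protein_id[1], start = c(out_s, ms),
               end = c(out_e, me), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  structure(out, class = c("slim_disorder", "data.frame"))
}

#' Read a flat term-to-protein annotation map
#'
#' Rows are `(term_id, protein_id[, term_name])`. Every protein id must be in
#' the proteome; empty terms cannot arise from the flat format.
#'
#' @param path TSV path.
#' @param prot A [proteome()].
#' @return A `slim_terms`: named list term_id -> character vector of protein
#'   ids, with a `term_names` attribute where names were given.
#' @export
read_term_map <- function(path, prot) {
  df <- read_tsv_raw(path, 2L)
  term_map(stats::setNames(df[[2]], df[[1]]), prot,
           term_names = if (ncol(df) >= 3) stats::setNames(df[[3]], df[[1]]))
}

#' Construct a term map from (term, protein) pairs
#'
#' @param pairs Named character vector: names are term ids, values protein ids.
#' @param prot A [proteome()].
#' @param term_names Optional named vector of display names.
#' @return A `slim_terms` list.
#' @export
term_map <- function(pairs, prot, term_names = NULL) {
  missing <- setdiff(unique(pairs), names(prot))
  if (length(missing))
    stop("term map references unknown protein(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  lst <- lapply(split(unname(pairs), names(pairs)), unique)
  if (any(lengths(lst) == 0)) stop("empty term set(s)")
  if (!is.null(term_names)) {
    tn <- term_names[!duplicated(names(term_names))]
    attr(lst, "term_names") <- tn
  }
  structure(lst, class = "slim_terms")
}

#' Read a known-motif catalog
#'
#' Rows are `(name, pattern, context-tag)`; patterns use the motif dialect of
#' [parse_motif()]. An unparseable pattern is an error naming the line.
#'
#' @param path TSV path.
#' @return A `slim_catalog` data frame with columns `name`, `pattern`,
#'   `context`, and a `motifs` attribute holding the parsed patterns.
#' @export
read_motif_catalog <- function(path) {
  df <- read_tsv_raw(path, 2L)
  names(df)[1:2] <- c("name", "pattern")
  df$context <- if (ncol(df) >= 3) df[[3]] else ""
  motifs <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    motifs[[i]] <- tryCatch(parse_motif(df$pattern[i]), error = function(e)
      stop("catalog line ", i, " ('", df$pattern[i], "'): ",
           conditionMessage(e), call. = FALSE))
  }
  out <- df[c("name", "pattern", "context")]
  attr(out, "motifs") <- motifs
  structure(out, class = c("slim_catalog", "data.frame"))
}

fmt_num <- function(x) formatC(x, digits = 10, format = "g")

#' Write discovery results to an output directory
#'
#' Writes `motifs.tsv` (motif string, MI bits, z-score, empirical p,
#' robustness, carrier count, seed k-mer), `heatmap.tsv` (per-class signed
#' enrichment scores and significance flags), `instances.tsv` (motif,
#' protein, 0-based start), and one PWM TSV per motif under `pwm/` (20
#' alphabetical residue columns, rows summing to 1). Output is deterministic
#' given the results.
#'
#' @param results A list of motif results as returned by [discover_motifs()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(results, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  if (file.access(out_dir, 2) != 0) stop("unwritable directory: ", out_dir)
  paths <- character(0)

  rows <- lapply(results, function(r) data.frame(
    motif = format(r$motif), mi_bits = fmt_num(r$mi),
    z_score = fmt_num(r$test$z_score),
    empirical_p = fmt_num(r$test$empirical_p),
    robustness = r$robustness, n_carriers = sum(r$profile$present),
    seed_kmer = r$seed_kmer, stringsAsFactors = FALSE))
  mt <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = character(0), mi_bits = character(0),
               z_score = character(0), empirical_p = character(0),
               robustness = integer(0), n_carriers = integer(0),
               seed_kmer = character(0))
  p <- file.path(out_dir, "motifs.tsv")
  utils::write.table(mt, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  hm <- lapply(results, function(r) {
    e <- r$enrichment
    row <- c(list(motif = format(r$motif)),
             stats::setNames(as.list(fmt_num(e$signed_score)),
                             paste0("score_", e$class_label)),
             stats::setNames(as.list(as.integer(e$significant)),
                             paste0("sig_", e$class_label)))
    as.data.frame(row, stringsAsFactors = FALSE, check.names = FALSE)
  })
  hmdf <- if (length(hm)) do.call(rbind, hm) else
    data.frame(motif = character(0))
  p <- file.path(out_dir, "heatmap.tsv")
  utils::write.table(hmdf, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  inst <- lapply(results, function(r) {
    pr <- r$profile
    n_i <- lengths(pr$instances)
    data.frame(motif = format(r$motif),
               protein_id = rep(pr$ids, n_i),
               start = unlist(pr$instances, use.names = FALSE),
               stringsAsFactors = FALSE)
  })
  idf <- if (length(inst)) do.call(rbind, inst) else
    data.frame(motif = character(0), protein_id = character(0),
               start = integer(0))
  p <- file.path(out_dir, "instances.tsv")
  utils::write.table(idf, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  if (length(results)) {
    pwmdir <- file.path(out_dir, "pwm")
    dir.create(pwmdir, showWarnings = FALSE)
    for (r in results) {
      if (!sum(r$profile$present) || is.null(r$pwm)) next
      pwm <- r$pwm
      pdf <- as.data.frame(apply(pwm, 2, fmt_num))
      if (nrow(pwm) == 1) pdf <- as.data.frame(t(pdf))
      colnames(pdf) <- colnames(pwm)
      p <- file.path(pwmdir, paste0(format(r$motif), ".tsv"))
      utils::write.table(pdf, p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
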