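# Readers and writers for the plain-text formats the pipeline touches.
# All genomic coordinates are 0-based half-open and stay that way throughout.

read_tab_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

.as_coord <- function(x, what, lineno) {
  v <- suppressWarnings(as.integer(x))
  bad <- is.na(v)
  if (any(bad)) {
    stop("non-integer ", what, " at line ", lineno[which(bad)[1]], call. = FALSE)
  }
  v
}

.check_interval <- function(start, end, lineno, what = "interval") {
  bad <- start < 0 | start >= end
  if (any(bad)) {
    i <- which(bad)[1]
    stop("invalid ", what, " at line ", lineno[i],
         ": start=", start[i], " end=", end[i],
         " (need 0 <= start < end)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read ChIA-PET interactions from a BEDPE-style file
#'
#' Each data line holds the two anchors of one DNA-DNA interaction:
#' `chrom1 start1 end1 chrom2 start2 end2 [name ...]`, tab-separated,
#' 0-based half-open coordinates. Lines starting with `#` are skipped.
#' Columns beyond the seventh are ignored; when the name column is absent
#' the interaction id is `I<line-number>`.
#'
#' @param path path to a BEDPE-like text file.
#' @return a data frame of class `cmn_interactions` with columns
#'   `id`, `chrom1`, `start1`, `end1`, `chrom2`, `start2`, `end2`.
#' @export
read_interactions <- function(path) {
  tl <- read_tab_lines(path)
  if (length(tl$lines) == 0) return(empty_interactions())
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6)) {
    stop("line ", tl$lineno[which(nf < 6)[1]],
         ": expected >= 6 tab-separated columns", call. = FALSE)
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  start1 <- .as_coord(get(2), "start1", tl$lineno)
  end1   <- .as_coord(get(3), "end1", tl$lineno)
  start2 <- .as_coord(get(5), "start2", tl$lineno)
  end2   <- .as_coord(get(6), "end2", tl$lineno)
  .check_interval(start1, end1, tl$lineno, "anchor A")
  .check_interval(start2, end2, tl$lineno, "anchor B")
  id <- ifelse(nf >= 7, vapply(fields, function(f) f[7], character(1)),
               paste0("I", tl$lineno))
  if (anyDuplicated(id)) {
    stop("duplicate interaction id: ", id[duplicated(id)][1], call. = FALSE)
  }
  out <- data.frame(id = id,
                    chrom1 = get(1), start1 = start1, end1 = end1,
                    chrom2 = get(4), start2 = start2, end2 = end2,
                    stringsAsFactors = FALSE)
  class(out) <- c("cmn_interactions", "data.frame")
  out
}

empty_interactions <- function() {
  out <- data.frame(id = character(), chrom1 = character(), start1 = integer(),
                    end1 = integer(), chrom2 = character(), start2 = integer(),
                    end2 = integer(), stringsAsFactors = FALSE)
  class(out) <- c("cmn_interactions", "data.frame")
  out
}

#' Write interactions back to BEDPE
#' @param x a `cmn_interactions` data frame.
#' @param path output path.
#' @export
write_interactions <- function(x, path) {
  df <- x[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "id")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_bed3 <- function(path) {
  tl <- read_tab_lines(path)
  if (length(tl$lines) == 0) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("line ", tl$lineno[which(nf < 3)[1]], ": expected >= 3 BED columns",
         call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- .as_coord(vapply(fields, `[[`, character(1), 2), "start", tl$lineno)
  end   <- .as_coord(vapply(fields, `[[`, character(1), 3), "end", tl$lineno)
  .check_interval(start, end, tl$lineno, "BED interval")
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[4], character(1)), NA_character_)
  data.frame(chrom = chrom, start = start, end = end, name = name,
             stringsAsFactors = FALSE)
}

#' Read ChIP-seq peaks for a set of transcription factors
#'
#' Two dialects are accepted: a named vector/list of per-TF BED3+ files
#' (names are the TF names), or a single BED file whose fourth column names
#' the TF of each peak. Overlapping peaks are kept as-is (no merging).
#'
#' @param paths named character vector of BED file paths (one per TF), or a
#'   single unnamed path to a combined BED with TF names in column 4.
#' @return a named list of data frames (`chrom`, `start`, `end`), one per TF
#'   (class `cmn_peaks`).
#' @export
read_peaks <- function(paths) {
  if (is.list(paths)) paths <- unlist(paths)
  if (length(paths) == 1 && is.null(names(paths))) {
    bed <- read_bed3(paths)
    if (any(is.na(bed$name))) {
      stop("combined peak BED requires TF names in column 4", call. = FALSE)
    }
    sets <- split(bed[, c("chrom", "start", "end")], bed$name)
    sets <- lapply(sets, function(d) { rownames(d) <- NULL; d })
  } else {
    if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
      stop("per-TF peak files must be named by TF", call. = FALSE)
    }
    if (anyDuplicated(names(paths))) {
      stop("duplicate TF name: ", names(paths)[duplicated(names(paths))][1],
           call. = FALSE)
    }
    sets <- lapply(paths, function(p) read_bed3(p)[, c("chrom", "start", "end")])
  }
  structure(sets, class = "cmn_peaks")
}

#' Read a physical protein-protein interaction network
#'
#' Two-column tab-separated file of protein names, one undirected edge per
#' line. Reversed duplicates are merged; self-loops are dropped with a
#' warning.
#'
#' @param path path to the edge list.
#' @return an undirected simple [igraph][igraph::graph_from_data_frame] graph.
#' @export
read_ppi <- function(path) {
  tl <- read_tab_lines(path)
  if (length(tl$lines) == 0) return(igraph::make_empty_graph(directed = FALSE))
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2)) {
    stop("line ", tl$lineno[which(nf < 2)[1]],
         ": PPI lines need two protein names", call. = FALSE)
  }
  a <- vapply(fields, `[[`, character(1), 1)
  b <- vapply(fields, `[[`, character(1), 2)
  loops <- a == b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped from PPI", call. = FALSE)
    a <- a[!loops]; b <- b[!loops]
  }
  ppi_graph(a, b)
}

#' Build a PPI graph from edge endpoint vectors
#' @param a,b character vectors of protein names (edge endpoints).
#' @return an undirected simple igraph graph.
#' @export
ppi_graph <- function(a, b) {
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  dup <- duplicated(key)
  a <- a[!dup]; b <- b[!dup]
  g <- igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a PPI graph as a two-column TSV edge list
#' @param g an igraph graph.
#' @param path output path.
#' @export
write_ppi <- function(g, path) {
  el <- igraph::as_edgelist(g)
  utils::write.table(el, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene expression matrix
#'
#' TSV with a header row of sample names and gene names in the first column.
#' Correlation-based steps require at least three samples.
#'
#' @param path path to the TSV.
#' @return numeric matrix, genes in rows.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene row: ", genes[duplicated(genes)][1], call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values", call. = FALSE)
  rownames(m) <- genes
  m
}

#' Read a one-name-per-line list (e.g. nuclear-localized proteins)
#' @param path path to the text file.
#' @return character vector of unique names.
#' @export
read_name_list <- function(path) {
  tl <- read_tab_lines(path)
  unique(trimws(tl$lines))
}

fmt_num <- function(x) formatC(x, format = "g", digits = 15)

#' Write fitted CMNs, mixing proportions and run metadata
#'
#' Writes one TSV per CMN (edge, probability, cumulative probability,
#' selected flag for the given coverage), a `theta.tsv` matrix of
#' per-interaction CMN proportions (rows sum to 1), and `meta.txt` with all
#' fit parameters, the seed and a corpus checksum. Output is byte-identical
#' across runs with the same seed.
#'
#' @param fit a [cmn_fit] object.
#' @param path_prefix path prefix; files are `<prefix>_cmn<k>.tsv`,
#'   `<prefix>_theta.tsv`, `<prefix>_meta.txt`.
#' @param coverage cumulative-probability coverage used to flag selected
#'   top edges (default 0.5).
#' @return invisibly, the vector of file paths written.
#' @export
write_cmns <- function(fit, path_prefix, coverage = 0.5) {
  stopifnot(inherits(fit, "cmn_fit"))
  paths <- character(0)
  for (k in seq_len(fit$K)) {
    cmn <- extract_cmn(fit, k, coverage = coverage)
    ord <- cmn$order          # all tokens, probability-descending
    tab <- data.frame(edge = edge_labels(fit$vocabulary)[ord],
                      probability = fmt_num(fit$beta[k, ord]),
                      cumulative = fmt_num(cumsum(fit$beta[k, ord])),
                      selected = as.integer(seq_along(ord) <= nrow(cmn$edges)))
    p <- paste0(path_prefix, "_cmn", k, ".tsv")
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  theta <- fit$theta
  tp <- paste0(path_prefix, "_theta.tsv")
  ttab <- data.frame(interaction_id = rownames(theta),
                     apply(theta, 2, fmt_num))
  colnames(ttab) <- c("interaction_id", paste0("CMN", seq_len(ncol(theta))))
  utils::write.table(ttab, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  mp <- paste0(path_prefix, "_meta.txt")
  cfg <- fit$config
  meta <- c(paste0("package=cmnet ", as.character(utils::packageVersion("cmnet"))),
            paste0(names(cfg), "=", vapply(cfg, function(v)
              paste(format(v), collapse = ","), character(1))),
            paste0("K=", fit$K),
            paste0("corpus_checksum=", fit$corpus_checksum))
  writeLines(meta, mp)
  invisible(c(paths, tp, mp))
}

#' Serialize a corpus as vocabulary + bags TSVs
#' @param corpus a `cmn_corpus`.
#' @param path_prefix files are `<prefix>_vocab.tsv` and `<prefix>_bags.tsv`.
#' @export
write_corpus <- function(corpus, path_prefix) {
  vp <- paste0(path_prefix, "_vocab.tsv")
  utils::write.table(corpus$vocabulary, vp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rows <- lapply(names(corpus$bags), function(id) {
    bag <- corpus$bags[[id]]
    data.frame(interaction_id = id,
               token_id = as.integer(names(bag)),
               count = as.integer(bag), stringsAsFactors = FALSE)
  })
  bp <- paste0(path_prefix, "_bags.tsv")
  utils::write.table(do.call(rbind, rows), bp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(vp, bp))
}

#' Read a corpus serialized by [write_corpus]
#' @param path_prefix the prefix used at write time.
#' @return a `cmn_corpus`.
#' @export
read_corpus <- function(path_prefix) {
  vocab <- utils::read.delim(paste0(path_prefix, "_vocab.tsv"),
                             stringsAsFactors = FALSE)
  btab <- utils::read.delim(paste0(path_prefix, "_bags.tsv"),
                            stringsAsFactors = FALSE)
  ids <- unique(btab$interaction_id)
  bags <- lapply(ids, function(id) {
    d <- btab[btab$interaction_id == id, ]
    stats::setNames(as.integer(d$count), as.character(d$token_id))
  })
  names(bags) <- ids
  new_corpus(vocab, bags, info = list(source = path_prefix))
}
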