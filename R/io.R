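# Readers and writers for the package's external artifacts. All files are
# UTF-8 tab-separated text; lines starting with '#' are comments.

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

#' Read a gene-by-sample expression matrix
#'
#' Expects tab-separated text with sample identifiers in the first row and
#' gene identifiers in the first column (an optional corner label in the
#' header is tolerated). Duplicate gene identifiers are retained; collapsing
#' probes to gene symbols is a separate step ([collapse_to_genes()]).
#'
#' @param path Path to the TSV file.
#' @param transpose If `TRUE` the file is laid out samples-in-rows and is
#'   transposed after parsing.
#' @return A numeric matrix (genes x samples) with dimnames.
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path, transpose = FALSE) {
  parsed <- parse_matrix_lines(read_tsv_lines(path), path)
  m <- parsed$matrix
  if (transpose) m <- t(m)
  validate_expression_matrix(m)
  m
}

parse_matrix_lines <- function(tl, path) {
  lines <- tl$lines
  if (length(lines) < 2) stop("file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  data <- fields[-1]
  widths <- lengths(data)
  if (length(unique(widths)) != 1)
    stop("ragged rows in ", path, ": line ",
         tl$lineno[-1][which(widths != widths[1])[1]],
         " has ", widths[widths != widths[1]][1],
         " fields, expected ", widths[1])
  ncells <- widths[1] - 1L
  if (ncells < 2) stop("fewer than 2 samples in ", path)
  if (length(header) == ncells + 1L) {
    samples <- header[-1]                      # corner label present
  } else if (length(header) == ncells) {
    samples <- header
  } else {
    stop("malformed header in ", path, ": ", length(header),
         " fields for ", ncells, " data columns")
  }
  genes <- vapply(data, `[`, "", 1L)
  vals <- matrix(NA_real_, length(data), ncells)
  for (i in seq_along(data)) {
    v <- suppressWarnings(as.numeric(data[[i]][-1]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop("non-numeric value '", data[[i]][j + 1L], "' at gene '",
           genes[i], "', sample '", samples[j], "' in ", path)
    }
    vals[i, ] <- v
  }
  dimnames(vals) <- list(genes, samples)
  list(matrix = vals, header = header)
}

#' Write an expression matrix to tab-separated text
#'
#' @param m Numeric matrix with gene row names and sample column names.
#' @param path Output path.
#' @export
write_expression_matrix <- function(m, path) {
  validate_expression_matrix(m, min_genes = 1L)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, digits = 15),
                                        collapse = "\t"))
  writeLines(paste(rownames(m), body, sep = "\t"), con)
  invisible(path)
}

#' Read / write a pair-list
#'
#' The pair-list format is `gene1<TAB>gene2<TAB>relation<TAB>support` with an
#' optional header row; relation must be one of `pp`, `mm`, `pm`.
#'
#' @param path File path.
#' @return [read_pairlist()] returns a [pair_list()].
#' @export
read_pairlist <- function(path) {
  tl <- read_tsv_lines(path)
  if (!length(tl$lines)) return(pair_list())
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 4))
    stop("pair-list rows must have 4 tab-separated fields (", path, ", line ",
         tl$lineno[which(lengths(fields) != 4)[1]], ")")
  m <- do.call(rbind, fields)
  if (m[1, 3] %in% RELATIONS) start <- 1L else start <- 2L  # header row?
  if (start > nrow(m)) return(pair_list())
  m <- m[seq(start, nrow(m)), , drop = FALSE]
  rel_ok <- m[, 3] %in% RELATIONS
  if (!all(rel_ok))
    stop("unknown relation token '", m[!rel_ok, 3][1], "' at line ",
         tl$lineno[seq(start, length(tl$lineno))][which(!rel_ok)[1]],
         " of ", path)
  sup <- suppressWarnings(as.integer(m[, 4]))
  if (anyNA(sup))
    stop("non-integer support at line ",
         tl$lineno[seq(start, length(tl$lineno))][which(is.na(sup))[1]],
         " of ", path)
  pair_list(m[, 1], m[, 2], m[, 3], sup)
}

#' @param pl A [pair_list()].
#' @rdname read_pairlist
#' @export
write_pairlist <- function(pl, path) {
  stopifnot(inherits(pl, "pair_list"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("gene1\tgene2\trelation\tsupport", con)
  if (nrow(pl))
    writeLines(paste(pl$gene1, pl$gene2, pl$relation, pl$support, sep = "\t"),
               con)
  invisible(path)
}

#' Read / write a signed regulatory network
#'
#' Format: `regulator<TAB>target<TAB>type` with type in `ac`, `re`, `du`
#' (SynTReN-style naming; background genes may use a `bgr_` prefix and can
#' be added through `gene_universe`).
#'
#' @param path File path.
#' @param gene_universe Optional character vector of all genes (to include
#'   genes with no interactions).
#' @return [read_regnet()] returns a [signed_regnet()].
#' @export
read_regnet <- function(path, gene_universe = NULL) {
  if (is.null(gene_universe)) {   # recover background genes written by us
    raw <- readLines(path, encoding = "UTF-8")
    ux <- grep("^#\\s*universe_extra:", raw, value = TRUE)
    if (length(ux)) {
      extra <- strsplit(sub("^#\\s*universe_extra:\\s*", "", ux[1]), ",",
                        fixed = TRUE)[[1]]
      gene_universe <- NA  # filled below once interactions are known
      attr(gene_universe, "extra") <- trimws(extra)
    }
  }
  tl <- read_tsv_lines(path)
  if (!length(tl$lines))
    stop("regulatory network file has no interactions: ", path)
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 3))
    stop("regulatory network rows must have 3 tab-separated fields (", path,
         ", line ", tl$lineno[which(lengths(fields) != 3)[1]], ")")
  m <- do.call(rbind, fields)
  if (m[1, 3] %in% INTERACTION_TYPES) start <- 1L else start <- 2L
  m <- m[seq(start, nrow(m)), , drop = FALSE]
  ok <- m[, 3] %in% INTERACTION_TYPES
  if (!all(ok))
    stop("unknown interaction type '", m[!ok, 3][1], "' at line ",
         tl$lineno[seq(start, length(tl$lineno))][which(!ok)[1]],
         " of ", path)
  ints <- data.frame(regulator = m[, 1], target = m[, 2], type = m[, 3],
                     stringsAsFactors = FALSE)
  if (!is.null(gene_universe) && anyNA(gene_universe[1]))
    gene_universe <- c(unique(c(ints$regulator, ints$target)),
                       attr(gene_universe, "extra"))
  signed_regnet(ints, gene_universe = gene_universe)
}

#' @param net A [signed_regnet()].
#' @rdname read_regnet
#' @export
write_regnet <- function(net, path) {
  stopifnot(inherits(net, "signed_regnet"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("regulator\ttarget\ttype", con)
  i <- net$interactions
  writeLines(paste(i$regulator, i$target, i$type, sep = "\t"), con)
  # genes outside the interactions (e.g. background genes) go in a comment
  extra <- setdiff(net$gene_universe, unique(c(i$regulator, i$target)))
  if (length(extra))
    writeLines(paste0("# universe_extra: ", paste(extra, collapse = ",")),
               con)
  invisible(path)
}

#' Read a gene set (one identifier per line)
#'
#' @param path File path; `#` comment lines are ignored.
#' @param name Set name; defaults to the file name without extension.
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, name = NULL) {
  tl <- read_tsv_lines(path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_set(name, trimws(tl$lines))
}

#' Read a probe-to-symbol identifier mapping
#'
#' Two tab-separated columns: probe identifier, gene symbol (optional
#' header).
#'
#' @param path File path.
#' @return Named character vector (names = probes, values = symbols).
#' @export
read_mapping <- function(path) {
  tl <- read_tsv_lines(path)
  fields <- strsplit(tl$lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2))
    stop("mapping rows need 2 tab-separated columns (", path, ")")
  m <- do.call(rbind, lapply(fields, `[`, 1:2))
  if (identical(tolower(m[1, ]), c("probe", "symbol")))
    m <- m[-1, , drop = FALSE]
  stats::setNames(m[, 2], m[, 1])
}

as_mapping <- function(mapping) {
  if (is.data.frame(mapping)) {
    if (ncol(mapping) < 2) stop("mapping table needs two columns")
    mapping <- stats::setNames(as.character(mapping[[2]]),
                               as.character(mapping[[1]]))
  }
  if (is.null(names(mapping)) || !length(mapping))
    stop("mapping must be a non-empty named vector or two-column table")
  mapping
}

#' Collapse probe-level identifiers to gene symbols
#'
#' Networks are built at the probe level as the matrix is given; symbol-level
#' de-duplication happens on pair-lists only. For a pair-list, every edge is
#' re-expressed in gene symbols, edges with unmapped identifiers are dropped,
#' self-pairs arising from the mapping are removed, and each symbol pair
#' appears once per relation (maximum support kept; `pm` direction is
#' preserved). For an expression matrix, rows are renamed and unmapped rows
#' dropped; duplicate-symbol rows are retained, not averaged.
#'
#' Identifiers already present among the mapping's symbols are kept as-is,
#' which makes the operation idempotent.
#'
#' @param x A [pair_list()] or expression matrix.
#' @param mapping Named character vector (probe -> symbol) or two-column
#'   table, e.g. from [read_mapping()].
#' @return Object of the same type as `x`, in the symbol namespace.
#' @export
collapse_to_genes <- function(x, mapping) UseMethod("collapse_to_genes")

map_ids <- function(ids, mapping) {
  out <- unname(mapping[ids])
  already <- is.na(out) & ids %in% mapping
  out[already] <- ids[already]
  out
}

#' @export
collapse_to_genes.pair_list <- function(x, mapping) {
  mapping <- as_mapping(mapping)
  g1 <- map_ids(x$gene1, mapping)
  g2 <- map_ids(x$gene2, mapping)
  keep <- !is.na(g1) & !is.na(g2) & g1 != g2
  pair_list(g1[keep], g2[keep], x$relation[keep], x$support[keep])
}

#' @export
collapse_to_genes.matrix <- function(x, mapping) {
  mapping <- as_mapping(mapping)
  sym <- map_ids(rownames(x), mapping)
  out <- x[!is.na(sym), , drop = FALSE]
  rownames(out) <- sym[!is.na(sym)]
  out
}

#' Build a directed pair-list from an up and a down gene set
#'
#' All combinations of the up set (column 1) with the down set (column 2) in
#' the `pm` convention (gene1 up, gene2 down), self-pairs excluded. This is
#' how expected up-down relationships are assembled from two differential
#' gene lists (e.g. population-up vs population-down genes) before matching
#' them against inferred networks.
#'
#' @param up,down [gene_set()]s or character vectors.
#' @return A [pair_list()] of `pm` records with support 0 (expected, not yet
#'   observed).
#' @export
build_pairlist_from_sets <- function(up, down) {
  u <- as_gene_vector(up)
  d <- as_gene_vector(down)
  if (!length(u) || !length(d)) stop("up and down gene sets must be non-empty")
  g1 <- rep(u, times = length(d))
  g2 <- rep(d, each = length(u))
  keep <- g1 != g2
  pair_list(g1[keep], g2[keep], rep("pm", sum(keep)),
            rep(0L, sum(keep)))
}
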