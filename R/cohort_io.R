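#' @useDynLib gitnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats plogis qlogis rbinom rexp rnorm rpois runif setNames
#'   predict kmeans prcomp quantile median pchisq var
#' @importFrom utils head modifyList
NULL

# ---------------------------------------------------------------------------
# Domain containers
# ---------------------------------------------------------------------------

#' Construct a tumor cohort
#'
#' A cohort bundles, for each tumor, its cancer-type label, the set of genes
#' hit by somatic genomic alterations (SGAs), and a binary vector of
#' differentially expressed genes (DEGs), together with the three shared
#' vocabularies (SGA genes, DEG genes, cancer types).
#'
#' @param tumor_id character vector of unique tumor identifiers.
#' @param cancer_type character vector of cancer-type labels, one per tumor.
#' @param sga list of character vectors, one per tumor: the SGA-affected
#'   gene symbols of that tumor (possibly empty).
#' @param deg binary matrix, one row per tumor, one column per DEG gene;
#'   column names are the DEG vocabulary.
#' @param gene_vocab,deg_vocab,cancer_type_vocab optional explicit
#'   vocabularies. Defaults are the sorted union of observed symbols.
#' @return An object of class `sga_cohort`.
#' @export
new_cohort <- function(tumor_id, cancer_type, sga, deg,
                       gene_vocab = NULL, deg_vocab = NULL,
                       cancer_type_vocab = NULL) {
  tumor_id <- as.character(tumor_id)
  n <- length(tumor_id)
  if (anyDuplicated(tumor_id))
    stop("tumor ids must be unique; duplicated: ",
         paste(unique(tumor_id[duplicated(tumor_id)]), collapse = ", "))
  if (length(cancer_type) != n || length(sga) != n || nrow(deg) != n)
    stop("tumor_id, cancer_type, sga and deg must describe the same tumors")
  sga <- lapply(sga, as.character)
  names(sga) <- tumor_id
  deg <- as.matrix(deg)
  storage.mode(deg) <- "integer"
  if (!all(deg %in% c(0L, 1L)))
    stop("deg matrix entries must be binary (0/1)")
  if (is.null(deg_vocab)) deg_vocab <- colnames(deg)
  if (is.null(deg_vocab)) stop("deg matrix must have column names (DEG vocabulary)")
  if (is.null(gene_vocab)) gene_vocab <- sort(unique(unlist(sga, use.names = FALSE)))
  if (is.null(cancer_type_vocab)) cancer_type_vocab <- sort(unique(cancer_type))
  missing_genes <- setdiff(unique(unlist(sga, use.names = FALSE)), gene_vocab)
  if (length(missing_genes))
    stop("SGA genes absent from gene_vocab: ",
         paste(head(missing_genes, 5), collapse = ", "))
  if (!all(cancer_type %in% cancer_type_vocab))
    stop("cancer types absent from cancer_type_vocab")
  if (ncol(deg) != length(deg_vocab))
    stop("deg matrix has ", ncol(deg), " columns but deg_vocab has ",
         length(deg_vocab))
  dimnames(deg) <- list(tumor_id, deg_vocab)
  structure(
    list(tumor_id = tumor_id,
         cancer_type = setNames(as.character(cancer_type), tumor_id),
         sga = sga,
         deg = deg,
         gene_vocab = as.character(gene_vocab),
         deg_vocab = as.character(deg_vocab),
         cancer_type_vocab = as.character(cancer_type_vocab)),
    class = "sga_cohort")
}

#' Number of tumors in a cohort
#' @param x an `sga_cohort`.
#' @export
n_tumors <- function(x) length(x$tumor_id)

#' @export
print.sga_cohort <- function(x, ...) {
  cat(sprintf(paste0("<sga_cohort> %d tumors, %d SGA genes, %d DEG genes, ",
                     "%d cancer types\n"),
              n_tumors(x), length(x$gene_vocab), length(x$deg_vocab),
              length(x$cancer_type_vocab)))
  m <- lengths(x$sga)
  cat(sprintf("  SGAs per tumor: median %g (range %d-%d); DEG positive rate %.3f\n",
              median(m), min(m), max(m), mean(x$deg)))
  invisible(x)
}

#' Subset a cohort by tumor
#'
#' Vocabularies are retained in full so that matrices derived from subsets
#' stay aligned with the parent cohort.
#' @param x an `sga_cohort`.
#' @param i tumor ids (character) or indices.
#' @param ... unused.
#' @export
`[.sga_cohort` <- function(x, i, ...) {
  if (is.character(i)) {
    miss <- setdiff(i, x$tumor_id)
    if (length(miss)) stop("unknown tumor ids: ", paste(head(miss, 5), collapse = ", "))
    i <- match(i, x$tumor_id)
  }
  new_cohort(x$tumor_id[i], x$cancer_type[i], x$sga[i],
             x$deg[i, , drop = FALSE],
             gene_vocab = x$gene_vocab, deg_vocab = x$deg_vocab,
             cancer_type_vocab = x$cancer_type_vocab)
}

#' Extract one tumor's record
#' @param cohort an `sga_cohort`.
#' @param id a tumor id present in the cohort.
#' @return list with `tumor_id`, `cancer_type`, `sga_genes`, `deg_vector`.
#' @export
tumor_record <- function(cohort, id) {
  j <- match(id, cohort$tumor_id)
  if (is.na(j)) stop("unknown tumor id: ", id)
  list(tumor_id = id,
       cancer_type = unname(cohort$cancer_type[j]),
       sga_genes = cohort$sga[[j]],
       deg_vector = cohort$deg[j, ])
}

# ---------------------------------------------------------------------------
# Cohort files
#
# Dialect: tab-separated UTF-8 with header rows.  The SGA file has columns
# tumor_id, cancer_type, sga_genes (semicolon-joined gene list, empty string
# for none).  Leading '#'-comment lines may carry the full vocabularies so
# that symbols absent from every tumor survive a round trip.  The DEG file
# is a dense tumor x gene binary matrix (or an optional sparse triplet
# dialect: tumor_id, gene, value).
# ---------------------------------------------------------------------------

.vocab_comment <- function(key, vocab)
  paste0("# ", key, ": ", paste(vocab, collapse = ";"))

.parse_vocab_comments <- function(lines) {
  com <- lines[startsWith(lines, "#")]
  out <- list()
  for (ln in com) {
    m <- regmatches(ln, regexec("^# *([a-z_]+_vocab): *(.*)$", ln))[[1]]
    if (length(m) == 3)
      out[[m[2]]] <- if (nzchar(m[3])) strsplit(m[3], ";", fixed = TRUE)[[1]] else character()
  }
  out
}

#' Read a cohort from SGA and DEG files
#'
#' @param sga_path tab-separated file with columns `tumor_id`,
#'   `cancer_type`, `sga_genes` (semicolon-joined).
#' @param deg_path tab-separated binary tumor-by-gene matrix (header row of
#'   gene names, first column `tumor_id`), or a triplet file
#'   (`tumor_id`, `gene`, `value`) when `deg_format = "triplet"`.
#' @param deg_format `"dense"` (default) or `"triplet"`.
#' @return an [new_cohort()] object. Vocabularies are taken from `#`-comment
#'   headers when present, otherwise the sorted union of observed symbols.
#' @export
read_cohort <- function(sga_path, deg_path, deg_format = c("dense", "triplet")) {
  deg_format <- match.arg(deg_format)
  sga_lines <- readLines(sga_path, encoding = "UTF-8")
  vocabs <- .parse_vocab_comments(sga_lines)
  body <- sga_lines[!startsWith(sga_lines, "#")]
  if (!length(body)) stop("SGA file has no header row: ", sga_path)
  hdr <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  need <- c("tumor_id", "cancer_type", "sga_genes")
  if (!identical(hdr[1:3], need))
    stop("SGA file header must be 'tumor_id\tcancer_type\tsga_genes'")
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  rows <- rows[lengths(rows) > 0]
  bad <- which(!lengths(rows) %in% 2:3)
  if (length(bad))
    stop("malformed SGA line ", bad[1] + 1L, " in ", sga_path)
  tumor_id <- vapply(rows, `[`, "", 1L)
  cancer_type <- vapply(rows, `[`, "", 2L)
  genes <- lapply(rows, function(r) {
    g <- if (length(r) >= 3) r[3] else ""
    if (nzchar(g)) strsplit(g, ";", fixed = TRUE)[[1]] else character()
  })

  deg <- .read_deg(deg_path, deg_format)
  sga_only <- setdiff(tumor_id, rownames(deg))
  deg_only <- setdiff(rownames(deg), tumor_id)
  if (length(sga_only) || length(deg_only))
    stop("tumor sets of the SGA and DEG files differ; only in SGA file: [",
         paste(head(sga_only, 5), collapse = ", "), "]; only in DEG file: [",
         paste(head(deg_only, 5), collapse = ", "), "]")
  deg <- deg[tumor_id, , drop = FALSE]
  deg_vocab <- vocabs$deg_vocab %||% colnames(deg)
  extra <- setdiff(colnames(deg), deg_vocab)
  if (length(extra))
    stop("DEG genes absent from declared deg_vocab: ",
         paste(head(extra, 5), collapse = ", "))
  if (!identical(colnames(deg), deg_vocab)) {
    full <- matrix(0L, nrow(deg), length(deg_vocab),
                   dimnames = list(rownames(deg), deg_vocab))
    full[, colnames(deg)] <- deg
    deg <- full
  }
  new_cohort(tumor_id, cancer_type, genes, deg,
             gene_vocab = vocabs$gene_vocab,
             deg_vocab = deg_vocab,
             cancer_type_vocab = vocabs$cancer_type_vocab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_deg <- function(path, deg_format) {
  if (deg_format == "triplet") {
    tab <- utils::read.delim(path, colClasses = "character")
    if (!all(c("tumor_id", "gene", "value") %in% names(tab)))
      stop("triplet DEG file needs columns tumor_id, gene, value")
    ids <- sort(unique(tab$tumor_id)); gs <- sort(unique(tab$gene))
    m <- matrix(0L, length(ids), length(gs), dimnames = list(ids, gs))
    v <- suppressWarnings(as.integer(tab$value))
    if (any(is.na(v) | !v %in% c(0L, 1L)))
      stop("non-binary DEG value at triplet row ", which(is.na(v) | !v %in% c(0L, 1L))[1])
    m[cbind(tab$tumor_id, tab$gene)] <- v
    return(m)
  }
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!startsWith(lines, "#")]
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "tumor_id") stop("DEG matrix first column must be tumor_id")
  genes <- hdr[-1]
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  rows <- rows[lengths(rows) > 0]
  ragged <- which(lengths(rows) != length(hdr))
  if (length(ragged))
    stop("DEG matrix row ", ragged[1] + 1L, " has ", lengths(rows)[ragged[1]],
         " fields, expected ", length(hdr))
  ids <- vapply(rows, `[`, "", 1L)
  m <- matrix(0L, length(rows), length(genes), dimnames = list(ids, genes))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.integer(rows[[i]][-1]))
    bad <- which(is.na(v) | !v %in% c(0L, 1L))
    if (length(bad))
      stop("non-binary DEG cell at row ", i + 1L, ", column '", genes[bad[1]],
           "' of ", path)
    m[i, ] <- v
  }
  m
}

#' Write a cohort to SGA and DEG files
#'
#' Output is deterministic: tumors in cohort order, matrix columns in
#' vocabulary order, vocabularies recorded as `#`-comment headers so that
#' [read_cohort()] reproduces the cohort exactly.
#' @inheritParams read_cohort
#' @param cohort an `sga_cohort`.
#' @export
write_cohort <- function(cohort, sga_path, deg_path,
                         deg_format = c("dense", "triplet")) {
  deg_format <- match.arg(deg_format)
  con <- file(sga_path, "w", encoding = "UTF-8")
  on.exit(close(con), add = TRUE)
  writeLines(c(.vocab_comment("gene_vocab", cohort$gene_vocab),
               .vocab_comment("cancer_type_vocab", cohort$cancer_type_vocab),
               .vocab_comment("deg_vocab", cohort$deg_vocab),
               "tumor_id\tcancer_type\tsga_genes",
               paste(cohort$tumor_id, cohort$cancer_type,
                     vapply(cohort$sga, paste, "", collapse = ";"),
                     sep = "\t")), con)
  deg <- cohort$deg[, cohort$deg_vocab, drop = FALSE]
  con2 <- file(deg_path, "w", encoding = "UTF-8")
  on.exit(close(con2), add = TRUE)
  if (deg_format == "dense") {
    writeLines(c(paste(c("tumor_id", colnames(deg)), collapse = "\t"),
                 paste(rownames(deg),
                       apply(deg, 1, paste, collapse = "\t"),
                       sep = "\t")), con2)
  } else {
    idx <- which(deg == 1L, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    writeLines(c("tumor_id\tgene\tvalue",
                 if (nrow(idx))
                   paste(rownames(deg)[idx[, 1]], colnames(deg)[idx[, 2]], "1",
                         sep = "\t")), con2)
  }
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Annotations (gene -> functional terms)
# ---------------------------------------------------------------------------

#' Read a gene annotation map
#'
#' Either a two-column tab-separated file (`gene`, `term`; header optional
#' but recommended) or a GAF 2.x file (gene symbol in column 3, term id in
#' column 5; `!`-comment lines skipped).
#' @param path input file.
#' @param format `"tsv"` or `"gaf"`.
#' @return a named list mapping gene to a character vector of terms, of
#'   class `annotation_map`. Unknown genes yield `character(0)` via
#'   [annotation_terms()].
#' @export
read_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  lines <- readLines(path, encoding = "UTF-8")
  if (format == "gaf") {
    lines <- lines[!startsWith(lines, "!")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 5)
    if (length(bad)) stop("malformed GAF line ", bad[1], " in ", path)
    gene <- vapply(fields, `[`, "", 3L)
    term <- vapply(fields, `[`, "", 5L)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 2)
    if (length(bad)) stop("malformed annotation line ", bad[1], " in ", path)
    gene <- vapply(fields, `[`, "", 1L)
    term <- vapply(fields, `[`, "", 2L)
    if (length(gene) && gene[1] %in% c("gene", "Gene")) {
      gene <- gene[-1]; term <- term[-1]
    }
  }
  as_annotation_map(split(term, gene))
}

#' Build an annotation map from a named list
#' @param x named list: gene -> character vector of terms.
#' @export
as_annotation_map <- function(x) {
  x <- lapply(x, function(v) sort(unique(as.character(v))))
  structure(x[order(names(x))], class = "annotation_map")
}

#' Look up the annotation terms of a gene
#' @param map an `annotation_map`.
#' @param gene gene symbol.
#' @return character vector of terms; empty for unknown genes.
#' @export
annotation_terms <- function(map, gene) {
  t <- map[[gene]]
  if (is.null(t)) character() else t
}

# ---------------------------------------------------------------------------
# Embedding tables
# ---------------------------------------------------------------------------

#' Construct an embedding table
#' @param x numeric matrix with one row per identifier (rownames required).
#' @export
embedding_table <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) stop("embedding matrix needs rownames (identifiers)")
  if (anyDuplicated(rownames(x)))
    stop("duplicate identifier in embedding table: ",
         rownames(x)[duplicated(rownames(x))][1])
  if (!all(is.finite(x))) stop("embedding vectors must be finite")
  structure(x, class = c("embedding_table", "matrix", "array"))
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d identifiers x %d dimensions\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Read / write an embedding table
#'
#' Tab-separated: first column `id`, then the d coordinates. Values are
#' written with 17 significant digits so a round trip is lossless.
#' @param path file path.
#' @export
read_embedding_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1)
    stop("ragged embedding file: line ", which(widths != widths[1])[1],
         " has ", widths[widths != widths[1]][1], " fields, expected ", widths[1])
  hdr <- fields[[1]]
  if (hdr[1] != "id") stop("embedding file must start with an 'id' header column")
  ids <- vapply(fields[-1], `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate identifier in embedding file: ", ids[duplicated(ids)][1])
  vals <- vapply(fields[-1], function(f) as.numeric(f[-1]),
                 numeric(length(hdr) - 1L))
  m <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = length(hdr) - 1L)
  dimnames(m) <- list(ids, hdr[-1])
  embedding_table(m)
}

#' @rdname read_embedding_table
#' @param table an `embedding_table`.
#' @export
write_embedding_table <- function(table, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  d <- ncol(table)
  writeLines(paste(c("id", paste0("v", seq_len(d))), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(table)), function(i)
    paste(c(rownames(table)[i], sprintf("%.17g", table[i, ])), collapse = "\t"),
    "")
  writeLines(body, con)
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# Phenotype tables
# ---------------------------------------------------------------------------

#' Read / write a survival table
#'
#' Tab-separated columns `tumor_id`, `time` (nonnegative), `event` (0/1).
#' @param path file path.
#' @return data.frame with those columns.
#' @export
read_survival_table <- function(path) {
  tab <- utils::read.delim(path)
  if (!all(c("tumor_id", "time", "event") %in% names(tab)))
    stop("survival table needs columns tumor_id, time, event")
  if (any(tab$time < 0)) stop("survival times must be nonnegative")
  if (!all(tab$event %in% c(0, 1))) stop("event indicator must be 0/1")
  tab$tumor_id <- as.character(tab$tumor_id)
  tab
}

#' @rdname read_survival_table
#' @param tab survival data.frame.
#' @export
write_survival_table <- function(tab, path) {
  utils::write.table(tab[, c("tumor_id", "time", "event")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read / write a binary drug-response table
#'
#' Tab-separated: first column `sample_id`, one 0/1 column per drug
#' (missing values allowed as NA).
#' @param path file path.
#' @export
read_drug_response_table <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (names(tab)[1] != "sample_id")
    stop("drug-response table must start with a sample_id column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!all(m %in% c(0, 1, NA)))
    stop("drug-response labels must be 0/1 or NA")
  rownames(m) <- as.character(tab$sample_id)
  m
}

#' @rdname read_drug_response_table
#' @param responses matrix of 0/1/NA labels, rownames = sample ids.
#' @export
write_drug_response_table <- function(responses, path) {
  df <- data.frame(sample_id = rownames(responses), responses,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
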