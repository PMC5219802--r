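# Readers and writers for the plain-file formats the pipeline consumes
# and emits.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             comment.char = "", quote = "")
}

#' Read coding or protein sequences from FASTA
#'
#' @param path FASTA file.
#' @param type `"dna"` or `"protein"`.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  set <- if (type == "dna") Biostrings::readDNAStringSet(path)
         else Biostrings::readAAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(out))  # first token of the header
  out
}

#' Read gene coordinates from GFF3 or a coordinate TSV
#'
#' GFF3 input keeps rows of type `gene` and derives the 1-based ordinal
#' gene rank per chromosome from start positions. TSV input expects
#' columns `gene`, `chromosome`, `ordinal_index`, `start_bp`, `strand`.
#'
#' @param path a `.gff3`/`.gff` file or a tab-separated coordinate table.
#' @return data.frame with `gene`, `chromosome`, `ordinal_index`,
#'   `start_bp`, `strand`.
#' @export
read_gene_coords <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 9L)
    if (length(bad)) stop("GFF3 line ", bad[1L], ": expected 9 columns")
    m <- do.call(rbind, fields)
    m <- m[m[, 3] == "gene", , drop = FALSE]
    ids <- sub("^.*ID=([^;]+).*$", "\\1", m[, 9])
    co <- data.frame(gene = ids, chromosome = m[, 1],
                     start_bp = as.integer(m[, 4]), strand = m[, 7],
                     stringsAsFactors = FALSE)
    co <- co[order(co$chromosome, co$start_bp), ]
    co$ordinal_index <- stats::ave(co$start_bp, co$chromosome,
                                   FUN = seq_along)
    rownames(co) <- NULL
    return(co[, c("gene", "chromosome", "ordinal_index", "start_bp",
                  "strand")])
  }
  co <- read_tsv(path)
  stopifnot(all(c("gene", "chromosome", "ordinal_index") %in% names(co)))
  co
}

#' Read a two-column gene-family table (PLAZA style)
#'
#' @param path tab-separated file with columns `gene`, `family` (header
#'   optional; headerless files are accepted).
#' @return named character vector mapping gene to family.
#' @export
read_family_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("gene", first, ignore.case = TRUE)
  df <- read.table(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE)
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read gene-to-GO annotations (one gene/term pair per line)
#'
#' @param path tab-separated file with columns `gene`, `term`.
#' @return data.frame with `gene`, `term`.
#' @export
read_go_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("gene", first, ignore.case = TRUE)
  df <- read.table(path, sep = "\t", header = has_header,
                   stringsAsFactors = FALSE)
  names(df)[1:2] <- c("gene", "term")
  df[, c("gene", "term")]
}
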