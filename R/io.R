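## File interchange: GFF3 / FASTA / BED via Bioconductor importers, TSV and
## JSON for tables and motif text formats.

#' Write a gene annotation to GFF3
#'
#' @param annotation annotation data.frame (gene_id, chrom, start, end,
#'   strand, haplotype, chrom_pair, rank, role), 1-based inclusive.
#' @param path output path.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(annotation$start, annotation$end),
    strand = annotation$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "allelome", type = "gene", ID = annotation$gene_id,
    haplotype = annotation$haplotype,
    chrom_pair = as.integer(annotation$chrom_pair),
    rank = as.integer(annotation$rank), role = annotation$role)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a gene annotation from GFF3
#'
#' @param path GFF3 file written by [write_annotation_gff3()].
#' @return annotation data.frame.
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  df <- data.frame(gene_id = gr$ID,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   haplotype = gr$haplotype,
                   chrom_pair = as.integer(gr$chrom_pair),
                   rank = as.integer(gr$rank), role = gr$role,
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$rank), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

#' Write sequences to FASTA
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "DNAStringSet"))
    seqs <- Biostrings::DNAStringSet(unlist(as.list(seqs)))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write / read the count matrix and sample sheet
#' @param counts integer matrix genes x samples.
#' @param sample_sheet data.frame (sample_id, tissue).
#' @param counts_path,samples_path output paths.
#' @export
write_counts <- function(counts, sample_sheet, counts_path, samples_path) {
  write_tsv(data.frame(gene_id = rownames(counts), counts,
                       check.names = FALSE), counts_path)
  write_tsv(sample_sheet, samples_path)
  invisible(counts_path)
}

#' @rdname write_counts
#' @return `read_counts`: list with `counts` and `sample_sheet`.
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- read_tsv(counts_path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$gene_id
  storage.mode(counts) <- "integer"
  list(counts = counts, sample_sheet = read_tsv(samples_path))
}

#' Write / read TE intervals as BED (0-based half-open)
#' @param te data.frame (chrom, start, end, te_id).
#' @param path BED path.
#' @export
write_te_bed <- function(te, path) {
  gr <- GenomicRanges::GRanges(te$chrom,
                               IRanges::IRanges(te$start + 1L, te$end),
                               name = te$te_id)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_te_bed
#' @export
read_te_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             te_id = gr$name, stringsAsFactors = FALSE)
}

#' Write a motif set in minimal MEME format
#' @param motifs list of [pwm()] objects.
#' @param path output path.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", BASES, motifs[[1]]$background),
                     collapse = " "), ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$motif_id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      ncol(m$mat)), con)
    for (j in seq_len(ncol(m$mat)))
      writeLines(paste(sprintf("%.6f", m$mat[, j]), collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from minimal MEME text
#' @param path MEME-format file.
#' @param pseudocount pseudocount for the resulting PWMs.
#' @return list of [pwm()] objects.
#' @export
read_meme <- function(path, pseudocount = 1e-8) {
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    tok <- strsplit(trimws(lines[bg_i[1] + 1L]), "\\s+")[[1]]
    vals <- as.numeric(tok[seq(2, length(tok), by = 2)])
    names(vals) <- tok[seq(1, length(tok), by = 2)]
    bg <- vals[BASES]
  }
  starts <- grep("^MOTIF", lines)
  lapply(starts, function(si) {
    id <- strsplit(trimws(lines[si]), "\\s+")[[1]][2]
    hdr <- si + grep("letter-probability matrix",
                     lines[(si + 1):length(lines)])[1]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1):(hdr + w)]
    mat <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
    mat <- unname(t(mat))    # 4 x w, rows A C G T
    mat <- sweep(mat, 2, colSums(mat), "/")   # renormalize printed rounding
    pwm(id, mat, background = bg, pseudocount = pseudocount)
  })
}

#' Read motifs from JASPAR-style text
#'
#' Accepts the common 4-row count blocks
#' (`>ID name` then `A [ ... ]` etc.); counts are column-normalized.
#'
#' @param path JASPAR file.
#' @param pseudocount pseudocount for the resulting PWMs.
#' @return list of [pwm()] objects.
#' @export
read_jaspar <- function(path, pseudocount = 1e-8) {
  lines <- readLines(path)
  starts <- grep("^>", lines)
  lapply(starts, function(si) {
    id <- strsplit(sub("^>", "", lines[si]), "\\s+")[[1]][1]
    rows <- lines[si + 1:4]
    mat <- t(vapply(rows, function(r) {
      nums <- regmatches(r, gregexpr("[0-9.]+", r))[[1]]
      as.numeric(nums)
    }, numeric(length(regmatches(lines[si + 1],
                                 gregexpr("[0-9.]+", lines[si + 1]))[[1]]))))
    base_order <- toupper(substr(trimws(rows), 1, 1))
    mat <- mat[match(BASES, base_order), , drop = FALSE]
    mat <- sweep(mat, 2, colSums(mat), "/")
    pwm(id, mat, pseudocount = pseudocount)
  })
}

#' Write / read the k-mer histogram (two-column TSV)
#' @param hist data.frame (depth, count).
#' @param path output path.
#' @export
write_kmer_histogram <- function(hist, path) write_tsv(hist, path)

#' @rdname write_kmer_histogram
#' @export
read_kmer_histogram <- function(path) read_tsv(path)

#' Write / read a generic results table
#' @param df data.frame.
#' @param path TSV path.
#' @export
write_table_tsv <- function(df, path) write_tsv(df, path)

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) read_tsv(path)
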