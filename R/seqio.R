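#' Read protein sequences from FASTA
#'
#' Reads a (possibly empty) protein FASTA file into an
#' [Biostrings::AAStringSet]. Record ids are the first whitespace-delimited
#' token of each header; the full header is kept in the `description`
#' metadata column. Residues are uppercased and validated against the
#' 20-letter amino-acid alphabet plus the ambiguity code `X`.
#'
#' @param path path to a FASTA file.
#' @return an `AAStringSet` with a `description` metadata column.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank)) {
    first <- nonblank[1L]
    if (!startsWith(trimws(lines[first]), ">"))
      stop(sprintf("malformed FASTA: sequence data before first header at line %d", first))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    out <- Biostrings::AAStringSet()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = character(0))
    return(out)
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  res <- toupper(as.character(set))
  bad <- lapply(strsplit(res, ""), function(ch) setdiff(unique(ch), AA_ALPHABET_X))
  offending <- which(lengths(bad) > 0L)
  if (length(offending)) {
    i <- offending[1L]
    stop(sprintf("illegal character '%s' in record '%s'", bad[[i]][1L], ids[i]))
  }
  if (any(!nzchar(res)))
    stop("empty sequence in record '", ids[which(!nzchar(res))[1L]], "'")
  out <- Biostrings::AAStringSet(res)
  names(out) <- ids
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = headers)
  out
}

#' Write protein sequences to FASTA
#'
#' @param seqs an `AAStringSet` (descriptions in `mcols(seqs)$description`
#'   are used as full headers when present).
#' @param path output path.
#' @export
writeProteinFasta <- function(seqs, path) {
  out <- seqs
  desc <- S4Vectors::mcols(seqs)$description
  if (!is.null(desc)) names(out) <- desc
  Biostrings::writeXStringSet(out, path)
  invisible(path)
}

#' Read a protein multiple alignment
#'
#' Reads an aligned FASTA or Stockholm file into an
#' [Biostrings::AAMultipleAlignment]. Gap characters are normalized to `-`
#' (Stockholm `.` insert gaps included) and residues are uppercased.
#'
#' @param path path to the alignment file.
#' @param dialect "afa" (aligned FASTA) or "stockholm".
#' @return an `AAMultipleAlignment`.
#' @export
readProteinAlignment <- function(path, dialect = c("afa", "stockholm")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "afa") {
    raw <- Biostrings::readBStringSet(path)
    w <- Biostrings::width(raw)
    if (length(unique(w)) > 1L) {
      off <- sub("\\s.*$", "", names(raw))[w != max(w)]
      stop("ragged alignment; offending ids: ", paste(off, collapse = ", "))
    }
    chars <- chartr(".", "-", toupper(as.character(raw)))
    aln <- Biostrings::AAMultipleAlignment(chars)
    names(aln@unmasked) <- sub("\\s.*$", "", names(raw))
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    chars <- chartr(".", "-", toupper(as.character(aln)))
    aln <- Biostrings::AAMultipleAlignment(chars)
  }
  aln
}

#' Write a multiple alignment as aligned FASTA
#'
#' @param aln an `AAMultipleAlignment` or named character vector of
#'   equal-length gapped strings.
#' @param path output path.
#' @export
writeProteinAlignment <- function(aln, path) {
  if (is(aln, "AAMultipleAlignment")) aln <- as.character(aln)
  stopifnot(length(unique(nchar(aln))) <= 1L)
  set <- Biostrings::BStringSet(aln)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' De-gap alignment members
#'
#' @param aln an `AAMultipleAlignment` or named character vector.
#' @return an `AAStringSet` of the unaligned member sequences.
#' @export
degapAlignment <- function(aln) {
  if (is(aln, "AAMultipleAlignment")) aln <- as.character(aln)
  Biostrings::AAStringSet(gsub("-", "", aln, fixed = TRUE))
}

.neighborhood_tsv_cols <- c("contig", "start", "end", "strand", "locus_tag", "product")

#' Read a gene neighborhood around a focal locus
#'
#' Reads gene features from GFF3 (via rtracklayer) or from a simple TSV
#' dialect (columns contig, start, end, strand, locus_tag, product;
#' 1-based inclusive coordinates) and extracts the focal gene plus up to
#' `windowGenes` features on each side of it on the same contig, ordered
#' by start. Windows at contig edges are truncated, never padded.
#'
#' @param path feature file.
#' @param dialect "gff3" or "tsv".
#' @param focalLocus locus tag of the amd gene; must occur exactly once.
#' @param windowGenes maximum number of genes retained on each side
#'   (default 10).
#' @return a [NeighborhoodRecord-class].
#' @export
readNeighborhood <- function(path, dialect = c("gff3", "tsv"), focalLocus,
                             windowGenes = 10L) {
  dialect <- match.arg(dialect)
  windowGenes <- as.integer(windowGenes)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    if (is.null(gr$locus_tag)) stop("GFF3 features lack a locus_tag attribute")
    if (is.null(gr$product)) gr$product <- NA_character_
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    miss <- setdiff(.neighborhood_tsv_cols, names(tab))
    if (length(miss)) stop("TSV neighborhood lacks columns: ", paste(miss, collapse = ", "))
    gr <- GenomicRanges::GRanges(tab$contig,
                                 IRanges::IRanges(tab$start, tab$end),
                                 strand = tab$strand)
    gr$locus_tag <- tab$locus_tag
    gr$product <- tab$product
  }
  hit <- which(gr$locus_tag == focalLocus)
  if (length(hit) == 0L) stop("focal locus '", focalLocus, "' not found")
  if (length(hit) > 1L) stop("focal locus '", focalLocus, "' is ambiguous (", length(hit), " features)")
  contig <- as.character(GenomicRanges::seqnames(gr))[hit]
  same <- gr[as.character(GenomicRanges::seqnames(gr)) == contig]
  same <- same[order(GenomicRanges::start(same))]
  i <- which(same$locus_tag == focalLocus)
  keep <- max(1L, i - windowGenes):min(length(same), i + windowGenes)
  new("NeighborhoodRecord", focalLocus = focalLocus,
      features = same[keep], windowGenes = windowGenes)
}

#' Write gene features as GFF3
#'
#' @param features a `GRanges` with `locus_tag` and `product` metadata
#'   columns, or a `NeighborhoodRecord`.
#' @param path output path.
#' @export
writeNeighborhoodGff3 <- function(features, path) {
  if (is(features, "NeighborhoodRecord")) features <- features@features
  gr <- features
  gr$ID <- gr$locus_tag
  gr$type <- "CDS"
  gr$source <- "amdscreen"
  gr$phase <- 0L
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

.habitat_vocab <- c("soil", "plant", "wastewater", "ocean", "host", "air",
                    "not specified")
.class_vocab <- c("Alpha-proteobacteria", "Beta-proteobacteria",
                  "Gamma-proteobacteria", "other")

#' Read a strain metadata table
#'
#' Reads a TSV with (at least) columns strain, class, genus, habitat and
#' locus_tag, in the style of a strain/locus-tag supplementary table.
#' Taxonomic classes are validated against the controlled vocabulary
#' Alpha-/Beta-/Gamma-proteobacteria plus "other"; blank or unknown
#' habitats are mapped to "not specified"; locus tags must be unique.
#'
#' @param path TSV path.
#' @return a data.frame with validated columns.
#' @export
readStrainMetadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("strain", "class", "genus", "habitat", "locus_tag")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("metadata table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$locus_tag))
    stop("duplicate locus_tag: ",
         paste(unique(tab$locus_tag[duplicated(tab$locus_tag)]), collapse = ", "))
  badc <- setdiff(unique(tab$class), .class_vocab)
  if (length(badc))
    stop("taxonomy class outside controlled vocabulary: ", paste(badc, collapse = ", "))
  hab <- tab$habitat
  hab[is.na(hab) | !(hab %in% .habitat_vocab)] <- "not specified"
  tab$habitat <- hab
  tab[, c(need, setdiff(names(tab), need))]
}

#' Write a strain metadata table
#'
#' @param meta data.frame as returned by [readStrainMetadata()].
#' @param path output TSV path.
#' @export
writeStrainMetadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

setMethod("show", "NeighborhoodRecord", function(object) {
  cat("NeighborhoodRecord around", object@focalLocus, "\n")
  cat(" ", length(object@features), "features, window", object@windowGenes,
      "genes each side\n")
  prod <- object@features$product
  cat("  products:", paste(utils::head(prod, 5L), collapse = " | "),
      if (length(prod) > 5L) "..." else "", "\n")
})
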