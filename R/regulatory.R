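#' Load gene models from GFF3 or BED
#'
#' Reads gene coding intervals via `rtracklayer::import`. BED input
#' (0-based half-open) is converted to the package's 1-based inclusive
#' convention; GFF3 input is filtered to `feature` rows (default `"gene"`).
#'
#' @param path GFF3 or BED file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param feature GFF3 feature type to keep.
#' @return data.frame with columns `id`, `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive coordinates).
#' @export
load_genes <- function(path, format = c("auto", "gff3", "bed"),
                       feature = "gene") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path, ignore.case = TRUE))
      "bed" else "gff3"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "bed") "BED" else "GFF3"),
    error = function(e) abort_stage(
      "regulatory_selection", paste0("cannot parse ", format, " '", path,
                                     "': ", conditionMessage(e)))
  )
  if (format == "gff3") {
    gr <- gr[as.character(gr$type) == feature]
    ids <- as.character(gr$ID %||% gr$Name %||% seq_along(gr))
    ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
  } else {
    ids <- if (!is.null(gr$name)) as.character(gr$name) else
      paste0("gene", seq_along(gr))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(!strand %in% c("+", "-")))
    abort_stage("regulatory_selection",
                "gene with unknown strand (need '+' or '-')")
  genes <- data.frame(id = ids,
                      chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = strand, stringsAsFactors = FALSE)
  if (anyDuplicated(genes$id))
    abort_stage("regulatory_selection", sprintf(
      "duplicate gene id '%s'", genes$id[duplicated(genes$id)][1]))
  genes
}

#' Expand gene coding intervals into regulatory windows
#'
#' Each gene interval is extended `up` bp upstream and `down` bp downstream
#' of the coding sequence (defaults 2 kb / 1 kb, the standard regulatory
#' window). With `strand_aware = TRUE` (default) "upstream" follows the
#' gene's strand: a minus-strand gene is extended `up` bp to the right and
#' `down` bp to the left. Windows are clipped at position 1.
#'
#' @param genes data.frame from [load_genes()].
#' @param up,down non-negative extensions in bp.
#' @param strand_aware if `FALSE`, all genes are treated as plus strand.
#' @return data.frame with columns `id`, `chrom`, `win_start`, `win_end`.
#' @export
expand_window <- function(genes, up = 2000, down = 1000,
                          strand_aware = TRUE) {
  stopifnot(up >= 0, down >= 0)
  minus <- strand_aware & genes$strand == "-"
  win_start <- ifelse(minus, genes$start - down, genes$start - up)
  win_end <- ifelse(minus, genes$end + up, genes$end + down)
  data.frame(id = genes$id, chrom = genes$chrom,
             win_start = pmax(1L, as.integer(win_start)),
             win_end = as.integer(win_end), stringsAsFactors = FALSE)
}

#' Select SNPs falling inside regulatory windows
#'
#' Returns the indices (in the original order) of loci whose (chrom, pos)
#' lies inside at least one window. Each locus is reported once regardless
#' of how many windows contain it; output is invariant under window
#' duplication and ordering. Warns when variant and window chromosome names
#' do not overlap.
#'
#' @param variants variant table from [read_vcf()].
#' @param windows data.frame from [expand_window()].
#' @return integer vector of selected locus indices.
#' @export
select_snps <- function(variants, windows) {
  vchr <- unique(variants$chrom)
  wchr <- unique(windows$chrom)
  if (length(intersect(vchr, wchr)) == 0 && nrow(windows) > 0) {
    warning(sprintf(
      "select_snps: no shared chromosome names (variants: %s; windows: %s)",
      paste(utils::head(vchr, 3), collapse = ","),
      paste(utils::head(wchr, 3), collapse = ",")))
  }
  snp <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, width = 1))
  win <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$win_start,
                                                 windows$win_end))
  hits <- GenomicRanges::findOverlaps(snp, win, ignore.strand = TRUE)
  sort(unique(S4Vectors::queryHits(hits)))
}

#' Map selected SNPs to the genes whose windows contain them
#'
#' @param variants variant table.
#' @param windows regulatory windows from [expand_window()].
#' @return data.frame with columns `locus` (key) and `genes`
#'   (comma-separated gene ids), one row per selected locus.
#' @export
snp_gene_map <- function(variants, windows) {
  snp <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, width = 1))
  win <- GenomicRanges::GRanges(windows$chrom,
                                IRanges::IRanges(windows$win_start,
                                                 windows$win_end))
  hits <- GenomicRanges::findOverlaps(snp, win, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  g <- windows$id[S4Vectors::subjectHits(hits)]
  keys <- locus_key(variants$chrom, variants$pos, variants$ref, variants$alt)
  sel <- sort(unique(q))
  data.frame(
    locus = keys[sel],
    genes = vapply(sel, function(i)
      paste(sort(unique(g[q == i])), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}
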