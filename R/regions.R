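# Region attribution of variants (promoters, UTRs, lncRNAs, exons/introns)
# and lineage polarization against primate outgroups.

REGION_CATEGORIES <- c("P1", "P2", "proximal_3UTR", "distal_3UTR", "exon",
                       "intron", "lncRNA_AL096865.1", "lncRNA_RUNX2-AS1",
                       "intergenic")

# precedence for the per-variant primary category:
# promoter > UTR > exon > lncRNA > intron > intergenic
CATEGORY_PRECEDENCE <- c("P1", "P2", "proximal_3UTR", "distal_3UTR", "exon",
                         "lncRNA_AL096865.1", "lncRNA_RUNX2-AS1", "intron",
                         "intergenic", "out_of_locus")

#' Build a region map
#'
#' Intervals are 0-based half-open internally (BED convention); categories
#' may overlap (e.g. the P2 promoter overlaps the antisense lncRNA
#' *AL096865.1*).
#'
#' @param chrom Chromosome name (recycled).
#' @param start,end 0-based half-open interval bounds.
#' @param category Region category per interval; one of
#'   `r paste(REGION_CATEGORIES, collapse = ", ")`.
#' @param assembly Assembly tag, default `"hg38"`.
#' @return A `GRanges` with metadata column `category`.
#' @export
region_map <- function(chrom, start, end, category, assembly = "hg38") {
  stopifnot(all(start < end))
  bad <- setdiff(category, REGION_CATEGORIES)
  if (length(bad))
    stop("unknown region categories: ", paste(bad, collapse = ", "))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end))
  gr$category <- category
  S4Vectors::metadata(gr)$assembly <- assembly
  gr
}

#' Read a region map from BED6
#'
#' The BED `name` field carries the region category.
#'
#' @param path Path to a BED file.
#' @param assembly Assembly tag.
#' @return A `GRanges` with metadata column `category`.
#' @export
read_region_bed <- function(path, assembly = "hg38") {
  gr <- rtracklayer::import(path, format = "BED")
  region_map(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
             gr$name, assembly = assembly)
}

#' Write a region map to BED6
#' @param map A `GRanges` region map.
#' @param path Output path.
#' @export
write_region_bed <- function(map, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(map)),
                   start = GenomicRanges::start(map) - 1L,
                   end = GenomicRanges::end(map),
                   name = map$category, score = 0L, strand = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Attribute variants to locus regions
#'
#' Every variant receives all categories whose intervals contain its 1-based
#' position (a 1-bp variant hits a half-open `[start, end)` interval iff its
#' position lies in `[start+1, end]`). Overlaps are kept: the per-category
#' counts therefore sum to at least the variant count. A single primary
#' category per variant is also reported, chosen by the precedence
#' promoter > UTR > exon > lncRNA > intron > intergenic. Variants inside the
#' locus but covered by no interval default to `intergenic`; variants
#' outside the locus bounds are flagged `out_of_locus`.
#'
#' @param calls A `variant_calls` data.frame (or any data.frame with a
#'   `position` column).
#' @param map A `GRanges` region map from [region_map()] /
#'   [read_region_bed()].
#' @param chrom Chromosome the variant positions refer to (must be present
#'   in the map).
#' @param locus Optional `c(start, end)` 0-based half-open locus bounds used
#'   for the `out_of_locus` flag; defaults to the span of the map.
#' @return A list with `table` (one row per variant: `position`,
#'   `categories` comma-joined, `primary_category`) and `counts` (named
#'   integer vector over all categories, overlap counting).
#' @export
annotate_variants <- function(calls, map, chrom = NULL, locus = NULL) {
  if (is.null(chrom)) chrom <- as.character(GenomicRanges::seqnames(map))[1]
  if (is.null(locus))
    locus <- c(min(GenomicRanges::start(map)) - 1L,
               max(GenomicRanges::end(map)))
  cats <- sort(unique(c(map$category, "intergenic")))
  empty_counts <- stats::setNames(integer(length(cats)), cats)
  if (nrow(calls) == 0L)
    return(list(table = data.frame(position = integer(0),
                                   categories = character(0),
                                   primary_category = character(0),
                                   stringsAsFactors = FALSE),
                counts = empty_counts))
  pos <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(start = calls$position, width = 1L))
  hits <- GenomicRanges::findOverlaps(pos, map)
  cat_list <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    k <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    ci <- unique(map$category[k])
    if (length(ci) == 0L) {
      in_locus <- calls$position[i] > locus[1] && calls$position[i] <= locus[2]
      ci <- if (in_locus) "intergenic" else "out_of_locus"
    }
    cat_list[[i]] <- ci
  }
  primary <- vapply(cat_list, function(ci)
    CATEGORY_PRECEDENCE[min(match(ci, CATEGORY_PRECEDENCE))], "")
  counts <- empty_counts
  tab <- table(unlist(cat_list))
  hit_cats <- intersect(names(tab), names(counts))
  counts[hit_cats] <- as.integer(tab[hit_cats])
  list(table = data.frame(position = calls$position,
                          categories = vapply(cat_list, paste, "",
                                              collapse = ","),
                          primary_category = primary,
                          stringsAsFactors = FALSE),
       counts = counts)
}

#' Polarize a variant against archaic hominins and primate outgroups
#'
#' Classifies the lineage on which a nucleotide difference arose.
#' `AMH_derived`: the modern-human allele differs from both archaics (which
#' agree) and every available outgroup carries the archaic allele — the
#' change is specific to anatomically modern humans. `archaic_specific`: the
#' divergent archaic allele is absent from all outgroups, which carry the
#' modern-human allele (the change arose on an archaic branch).
#' `archaic_shared_with_primates`: an archaic allele differing from AMH is
#' carried by every outgroup (the AMH state is the older change, or the
#' archaic state is conserved). Outgroup unanimity is required; any
#' disagreeing primate yields `ambiguous`. With no outgroups the class is
#' `ambiguous`, but when both archaics already disagree with AMH the
#' AMH-vs-archaic polarity is still reported with an `unpolarized` flag.
#'
#' @param species_alleles Named character vector of single bases. Must
#'   include `AMH` and at least one of `Neandertal`, `Denisovan`; any other
#'   names are treated as primate outgroups.
#' @return A list of class `lineage_call`: `class`, `amh_allele`,
#'   `archaic_alleles`, `outgroup_alleles`, `flags`.
#' @export
classify_lineage <- function(species_alleles) {
  alle <- toupper(species_alleles)
  if (!all(alle %in% VALID_BASES))
    stop("non-ACGT allele: ", paste(setdiff(alle, VALID_BASES), collapse = ","))
  if (!"AMH" %in% names(alle)) stop("AMH allele required")
  archaic_names <- intersect(c("Neandertal", "Denisovan"), names(alle))
  if (length(archaic_names) == 0L)
    stop("at least one archaic (Neandertal/Denisovan) allele required")
  amh <- alle[["AMH"]]
  archaics <- alle[archaic_names]
  outgroups <- alle[setdiff(names(alle), c("AMH", archaic_names))]
  diff_arch <- archaics[archaics != amh]
  if (length(diff_arch) == 0L)
    stop("all species carry the AMH allele; no variant to classify")
  flags <- character(0)
  # the archaic allele under test: shared archaic state if both differ,
  # else the single divergent archaic's allele
  both_differ <- length(diff_arch) == length(archaics) &&
    length(unique(diff_arch)) == 1L
  arch_allele <- unique(diff_arch)[1]
  cls <- "ambiguous"
  if (length(unique(diff_arch)) > 1L) {
    cls <- "ambiguous"
  } else if (length(outgroups) == 0L) {
    cls <- "ambiguous"
    if (both_differ) flags <- c(flags, "unpolarized")
  } else if (length(unique(outgroups)) > 1L) {
    cls <- "ambiguous"
  } else {
    og <- unique(outgroups)
    if (og == arch_allele) {
      cls <- if (both_differ) "AMH_derived" else "archaic_shared_with_primates"
    } else if (og == amh) {
      cls <- "archaic_specific"
    } else {
      cls <- "ambiguous"
    }
  }
  structure(list(class = cls, amh_allele = amh, archaic_alleles = archaics,
                 outgroup_alleles = outgroups, flags = flags),
            class = "lineage_call")
}

#' Cross-tabulate variant kinds by region category
#'
#' @param calls A `variant_calls` data.frame.
#' @param annotation Result of [annotate_variants()] on the same calls.
#' @return A contingency table of `kind` (rows) by primary category
#'   (columns).
#' @export
kind_by_category <- function(calls, annotation) {
  stopifnot(nrow(calls) == nrow(annotation$table))
  table(kind = calls$kind, category = annotation$table$primary_category)
}
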