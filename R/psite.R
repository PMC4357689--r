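#' Length-dependent P-site offset
#'
#' Maps ribosome-protected-fragment length to the distance (in nt) from the
#' 5' end of the alignment to the ribosomal P-site: +12 for fragments of at
#' most 30 nt, +13 for 31-33 nt and +14 for 34 nt. Fragments outside the
#' 26-34 nt range are not informative ribosome footprints and are rejected
#' (NA), to be counted as discarded by the caller.
#'
#' @param read_length integer vector of aligned fragment lengths (nt, after
#'   soft-clipping)
#' @return integer vector of offsets; NA where the length is rejected
#' @export
psite_offset <- function(read_length) {
  read_length <- as.integer(read_length)
  off <- rep(NA_integer_, length(read_length))
  ok <- !is.na(read_length) & read_length >= 26L & read_length <= 34L
  off[ok & read_length <= 30L] <- 12L
  off[ok & read_length >= 31L & read_length <= 33L] <- 13L
  off[ok & read_length == 34L] <- 14L
  off
}

# accept SAM transparently: convert to sorted+indexed BAM in tempdir
as_bam_path <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    suppressMessages(Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                                      overwrite = TRUE))
  } else path
}

#' Build a ribosome P-site occupancy profile from aligned reads
#'
#' Converts aligned RIBO-seq reads (SAM or BAM) into per-position P-site
#' counts. Each retained alignment contributes one count at its P-site: the
#' position reached by walking [psite_offset()] aligned reference bases from
#' the read's 5' end (the leftmost aligned base on the plus strand, the
#' rightmost on the minus strand). The walk skips intronic gaps (CIGAR N),
#' so a P-site never lands in an intron; soft-clipped bases are excluded
#' both from the walk and from the length used for the offset rule.
#'
#' Reads shorter than 26 nt or longer than 34 nt are discarded and counted.
#' Under `multimap = "unique"` reads reported at more than one location
#' (NH tag > 1) are discarded; under `"leq15"` reads at more than 15
#' locations are discarded and each retained multimapper contributes one
#' count at every reported location. QC stages use unique mappers only;
#' search-database construction additionally admits multimappers up to 15
#' locations.
#'
#' @param path SAM or BAM file of aligned reads (headers with @SQ required)
#' @param condition "elongating" (CHX) or "initiating" (LTM/HARR)
#' @param multimap "unique" or "leq15"
#' @param min_len,max_len retained fragment length range (nt)
#' @return an object of class `PsiteProfile`: list with `counts` (data.table
#'   chrom/strand/pos/count), `condition`, `multimap`, and bookkeeping totals
#'   (`total_records`, `total_retained`, `discarded_by_length`,
#'   `discarded_by_multimap`, `unmapped`)
#' @export
build_profile <- function(path,
                          condition = c("elongating", "initiating"),
                          multimap = c("unique", "leq15"),
                          min_len = 26L, max_len = 34L) {
  condition <- match.arg(condition)
  multimap <- match.arg(multimap)
  bam <- as_bam_path(path)

  total <- Rsamtools::countBam(bam)$records
  unmapped <- Rsamtools::countBam(
    bam, param = Rsamtools::ScanBamParam(
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)))$records

  gal <- GenomicAlignments::readGAlignments(
    bam, param = Rsamtools::ScanBamParam(tag = "NH"))
  if (any(as.character(GenomicAlignments::strand(gal)) == "*"))
    stop("alignment without strand information")

  cig <- GenomicAlignments::cigar(gal)
  rlen <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cig, after.soft.clipping = TRUE)
  off <- psite_offset(rlen)
  # override range if non-default requested
  if (min_len != 26L || max_len != 34L) {
    off[rlen < min_len | rlen > max_len] <- NA_integer_
  }
  nh <- S4Vectors::mcols(gal)$NH
  nh[is.na(nh)] <- 1L
  keep_mm <- if (multimap == "unique") nh == 1L else nh <= 15L

  disc_len <- sum(is.na(off))
  disc_mm <- sum(!keep_mm & !is.na(off))
  keep <- keep_mm & !is.na(off)

  counts <- data.table(chrom = character(), strand = character(),
                       pos = integer(), count = integer())
  if (any(keep)) {
    galk <- gal[keep]
    offk <- off[keep]
    blocks <- GenomicAlignments::grglist(galk)  # aligned ref blocks, introns split
    bdt <- as.data.table(blocks)[
      , .(group, chrom = as.character(seqnames), start, end, width)]
    bdt[, cw := cumsum(width), by = group]
    totw <- bdt[, sum(width), keyby = group]$V1  # group ids are 1..n
    str <- as.character(GenomicAlignments::strand(galk))
    # 1-based index of the P-site among the read's aligned reference
    # positions, counted in ascending genomic order
    tgt <- ifelse(str == "+", offk + 1L, totw - offk)
    tgt <- pmax(1L, pmin(tgt, totw))  # defensive clamp (offset < read length)
    bdt[, idx := tgt[group]]
    hit <- bdt[idx <= cw & idx > cw - width]  # exactly one block per read
    counts <- data.table(
      chrom = hit$chrom, strand = str[hit$group],
      pos = as.integer(hit$start + (hit$idx - (hit$cw - hit$width)) - 1L)
    )[, .(count = .N), by = .(chrom, strand, pos)]
  }
  setkey(counts, chrom, strand, pos)

  prof <- list(condition = condition, multimap = multimap,
               counts = counts,
               total_records = total,
               total_retained = sum(keep),
               discarded_by_length = disc_len,
               discarded_by_multimap = disc_mm,
               unmapped = unmapped)
  class(prof) <- "PsiteProfile"
  prof
}

#' @export
print.PsiteProfile <- function(x, ...) {
  cat("PsiteProfile (", x$condition, ", multimap=", x$multimap, "): ",
      x$total_retained, " P-sites at ", nrow(x$counts),
      " positions; discarded ", x$discarded_by_length, " by length, ",
      x$discarded_by_multimap, " by multimapping, ", x$unmapped,
      " unmapped\n", sep = "")
  invisible(x)
}

# build a profile directly from a position/count table (testing & oracles)
profile_from_counts <- function(counts, condition = "elongating",
                                multimap = "unique") {
  counts <- as.data.table(counts)
  stopifnot(all(c("chrom", "strand", "pos", "count") %in% names(counts)))
  counts <- counts[count > 0]
  counts[, `:=`(chrom = as.character(chrom), strand = as.character(strand),
                pos = as.integer(pos), count = as.integer(count))]
  setkey(counts, chrom, strand, pos)
  prof <- list(condition = condition, multimap = multimap, counts = counts,
               total_records = sum(counts$count),
               total_retained = sum(counts$count),
               discarded_by_length = 0L, discarded_by_multimap = 0L,
               unmapped = 0L)
  class(prof) <- "PsiteProfile"
  prof
}

# P-site counts at given (chrom, strand, positions); zeros where absent
profile_counts_at <- function(profile, chrom, strand, positions) {
  q <- data.table(chrom = chrom, strand = strand,
                  pos = as.integer(positions))
  res <- profile$counts[q, on = c("chrom", "strand", "pos")]
  out <- res$count
  out[is.na(out)] <- 0L
  out
}

#' Write a P-site profile as a BedGraph track
#'
#' Emits the per-position counts of one strand as a standard BedGraph file
#' (0-based half-open intervals), merging runs of adjacent positions with
#' equal counts. One file per strand per condition is the intended layout.
#'
#' @param profile a `PsiteProfile`
#' @param path output file
#' @param strand "+" or "-"
#' @param track_name optional track line name; NULL suppresses the track line
#' @return invisibly, the path
#' @export
write_bedgraph <- function(profile, path, strand = c("+", "-"),
                           track_name = NULL) {
  strand <- match.arg(strand)
  d <- profile$counts[strand, on = "strand"][!is.na(pos)]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name))
    writeLines(sprintf("track type=bedGraph name=\"%s\"", track_name), con)
  if (nrow(d)) {
    setorder(d, chrom, pos)
    d[, run := cumsum(!(chrom == data.table::shift(chrom, fill = "") &
                        pos == data.table::shift(pos, fill = -2L) + 1L &
                        count == data.table::shift(count, fill = -1L)))]
    out <- d[, .(chrom = chrom[1], start0 = pos[1] - 1L,
                 end = pos[.N], count = count[1]), by = run]
    writeLines(sprintf("%s\t%d\t%d\t%g",
                       out$chrom, out$start0, out$end, out$count), con)
  }
  invisible(path)
}

#' Read a BedGraph file back into per-position counts
#'
#' Inverse of [write_bedgraph()] for one strand: expands intervals to
#' 1-based per-position counts.
#'
#' @param path BedGraph file
#' @param strand strand label to attach
#' @return data.table with chrom/strand/pos/count
#' @export
read_bedgraph <- function(path, strand = "+") {
  lines <- readLines(path)
  lines <- lines[!grepl("^track|^#|^$", lines)]
  if (!length(lines))
    return(data.table(chrom = character(), strand = character(),
                      pos = integer(), count = integer()))
  d <- fread(text = lines, header = FALSE,
             col.names = c("chrom", "start0", "end", "count"))
  out <- d[, .(pos = seq.int(start0 + 1L, end)), by = .(chrom, start0, count)
           ][, .(chrom, strand = strand, pos, count = as.integer(count))]
  setkey(out, chrom, strand, pos)
  out[]
}
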