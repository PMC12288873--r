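#' Read a phased VCF into a haplotype matrix
#'
#' Parses a VCF with phased diploid genotypes (`a|b`) and splits every donor
#' into two haplotype rows (`_A` = left of the bar, `_B` = right). Only
#' biallelic records are kept; multiallelic records are skipped with a
#' warning. Variants carried by fewer than `min_haplotype_count` haplotypes
#' (total alternate-allele count across all haplotypes) are dropped —
#' rare variants carry little detectable correlation with the rest of the
#' panel and resist compression.
#'
#' @param path path to a VCF (plain text or gzipped).
#' @param min_haplotype_count minimum alternate-allele count for a variant
#'   to be retained; `0` keeps everything.
#' @return A [haplotype_matrix()] with `2 x n_donors` rows.
#' @export
read_phased_vcf <- function(path, min_haplotype_count = 3) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- rbind(fix)  # single-record VCF -> vector
  if (is.null(fix) || nrow(v@gt) == 0 && nrow(fix) == 0) {
    return(haplotype_matrix(matrix(integer(), 0, 0), numeric()))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  gt <- v@gt[, -1, drop = FALSE]  # drop FORMAT column
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  samples <- colnames(gt)
  # FORMAT may carry more than GT; keep the GT subfield
  fmt <- v@gt[, 1]
  gt_idx <- vapply(strsplit(fmt, ":", fixed = TRUE),
                   function(f) match("GT", f), integer(1))
  if (anyNA(gt_idx)) stopf("record without GT field (record %d)",
                           which(is.na(gt_idx))[1])

  multi <- grepl(",", fix$ALT %||% "", fixed = TRUE)
  if (any(multi)) {
    warnf("skipping %d multiallelic record(s)", sum(multi))
  }
  keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  gt_idx <- gt_idx[keep]
  m <- nrow(fix)
  n_hap <- 2L * length(samples)
  data <- matrix(0L, nrow = n_hap, ncol = max(m, 0L))
  if (m > 0) {
    for (i in seq_len(m)) {
      cells <- gt[i, ]
      gts <- vapply(strsplit(cells, ":", fixed = TRUE),
                    function(x) x[gt_idx[i]], character(1))
      if (anyNA(gts) || any(gts %in% c(".", "./.", ".|.")))
        stopf("missing genotype at %s:%s", fix$CHROM[i], fix$POS[i])
      if (any(grepl("/", gts, fixed = TRUE)))
        stopf("unphased genotype ('a/b') at %s:%s (sample %s)",
              fix$CHROM[i], fix$POS[i],
              samples[grep("/", gts, fixed = TRUE)[1]])
      parts <- strsplit(gts, "|", fixed = TRUE)
      if (any(lengths(parts) != 2))
        stopf("genotype is not diploid phased at %s:%s",
              fix$CHROM[i], fix$POS[i])
      al <- suppressWarnings(as.integer(unlist(parts)))
      if (anyNA(al)) stopf("missing allele in genotype at %s:%s",
                           fix$CHROM[i], fix$POS[i])
      # unlist order: sample1_A, sample1_B, sample2_A, ...
      data[, i] <- al
    }
  }
  pos <- as.numeric(fix$POS)
  ord <- order(pos)
  data <- data[, ord, drop = FALSE]
  pos <- pos[ord]
  ids <- fix$ID[ord]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix$CHROM[ord], "_", pos)[is.na(ids) | ids == "."]
  counts <- colSums(data)
  keep_var <- counts >= min_haplotype_count
  # rows were filled sample-major: sample1_A, sample1_B, sample2_A, ...
  hap_ids <- as.vector(rbind(paste0(samples, "_A"), paste0(samples, "_B")))
  haplotype_matrix(data[, keep_var, drop = FALSE], pos[keep_var],
                   chrom = if (m > 0) fix$CHROM[1] else "chr1",
                   variant_ids = ids[keep_var], sample_ids = hap_ids)
}

#' Write a haplotype matrix as a phased VCF
#'
#' Consecutive row pairs are taken as the two haplotypes of one donor and
#' written as phased `a|b` genotypes. Inverse of [read_phased_vcf()] with
#' `min_haplotype_count = 0`.
#'
#' @param hm a [haplotype_matrix()] with an even number of rows.
#' @param path output path (plain-text VCF).
#' @export
write_phased_vcf <- function(hm, path) {
  stopifnot(inherits(hm, "haplotype_matrix"))
  n <- nrow(hm$data)
  if (n %% 2 != 0)
    stopf("haplotype matrix has odd row count (%d); cannot pair donors", n)
  donors <- unique(sub("_[AB]$", "", hm$sample_ids))
  if (length(donors) != n / 2) donors <- paste0("donor", seq_len(n / 2))
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", hm$chrom),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", donors), collapse = "\t")
  )
  m <- ncol(hm$data)
  lines <- header
  if (m > 0) {
    a_rows <- hm$data[seq(1, n, by = 2), , drop = FALSE]
    b_rows <- hm$data[seq(2, n, by = 2), , drop = FALSE]
    recs <- vapply(seq_len(m), function(j) {
      gts <- paste0(a_rows[, j], "|", b_rows[, j])
      paste(c(hm$chrom, format(hm$positions[j], scientific = FALSE),
              hm$variant_ids[j], "A", "T", ".", "PASS", ".", "GT", gts),
            collapse = "\t")
    }, character(1))
    lines <- c(lines, recs)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a recombination-rate map
#'
#' Reads a tab-separated interval file with columns chrom, start, end and
#' rate (cM/Mb); a header row is detected and skipped. Only intervals on
#' `chrom` are returned, sorted by start. Coordinates are normalised to
#' 1-based inclusive-start / exclusive-end; `coords = "bed"` (default)
#' treats the input as 0-based half-open, `coords = "one-based"` as already
#' 1-based.
#'
#' @param path TSV file path.
#' @param chrom chromosome to extract.
#' @param coords coordinate dialect of the file.
#' @return A [recomb_map()].
#' @export
read_recomb_map <- function(path, chrom, coords = c("bed", "one-based")) {
  coords <- match.arg(coords)
  if (!file.exists(path)) stopf("no such file: %s", path)
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0) return(recomb_map())
  fields <- strsplit(raw, "\t", fixed = TRUE)
  first <- fields[[1]]
  has_header <- length(first) >= 4 &&
    is.na(suppressWarnings(as.numeric(first[2])))
  rows <- if (has_header) fields[-1] else fields
  lineno <- (if (has_header) 2L else 1L) - 1L + seq_along(rows)
  if (length(rows) == 0) return(recomb_map())
  bad <- which(lengths(rows) < 4)
  if (length(bad))
    stopf("line %d: expected 4 tab-separated columns", lineno[bad[1]])
  mat <- do.call(rbind, lapply(rows, `[`, 1:4))
  start <- suppressWarnings(as.numeric(mat[, 2]))
  end <- suppressWarnings(as.numeric(mat[, 3]))
  rate <- suppressWarnings(as.numeric(mat[, 4]))
  for (col in list(list(start, "start"), list(end, "end"), list(rate, "rate"))) {
    if (anyNA(col[[1]]))
      stopf("line %d: unparseable %s value",
            lineno[which(is.na(col[[1]]))[1]], col[[2]])
  }
  sel <- mat[, 1] == chrom
  if (coords == "bed") start <- start + 1
  recomb_map(chrom = mat[sel, 1], start = start[sel], end = end[sel],
             rate = rate[sel])
}

#' Write a recombination-rate map
#'
#' @param map a [recomb_map()].
#' @param path output TSV path.
#' @param coords coordinate dialect to emit (see [read_recomb_map()]).
#' @export
write_recomb_map <- function(map, path, coords = c("bed", "one-based")) {
  coords <- match.arg(coords)
  start <- map$start
  if (coords == "bed") start <- start - 1
  lines <- c("chrom\tstart\tend\trate",
             sprintf("%s\t%s\t%s\t%s", map$chrom,
                     format(start, scientific = FALSE, trim = TRUE),
                     format(map$end, scientific = FALSE, trim = TRUE),
                     format(map$rate, trim = TRUE)))
  writeLines(lines, path)
  invisible(path)
}

#' Save segmented haplotype data to a run directory
#'
#' Writes one tabular file per section (positions header plus binary
#' haplotype rows) and a JSON manifest recording section boundaries,
#' boundary provenance and counters. [load_segments()] restores the
#' submatrices bit-exactly.
#'
#' @param plan a [segmentation_plan] over `hm`.
#' @param hm a [haplotype_matrix()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
save_segments <- function(plan, hm, dir) {
  stopifnot(inherits(plan, "segmentation_plan"),
            inherits(hm, "haplotype_matrix"))
  validate_plan(plan, ncol(hm$data))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sec <- plan$sections
  files <- character(nrow(sec))
  for (k in seq_len(nrow(sec))) {
    sub <- subset_variants(hm, sec$first[k], sec$last[k])
    files[k] <- sprintf("section_%04d.tsv", k)
    con <- file.path(dir, files[k])
    lines <- c(
      paste0("#chrom=", hm$chrom),
      paste0("#positions=", paste(format(sub$positions, scientific = FALSE,
                                         trim = TRUE), collapse = ",")),
      paste(c("sample", sub$variant_ids), collapse = "\t"),
      vapply(seq_len(nrow(sub$data)), function(i) {
        paste(c(sub$sample_ids[i], sub$data[i, ]), collapse = "\t")
      }, character(1))
    )
    writeLines(lines, con)
  }
  manifest <- list(
    chrom = hm$chrom,
    n_variants = ncol(hm$data),
    n_haplotypes = nrow(hm$data),
    n_artificial = plan$n_artificial,
    n_ignored_hotspots = plan$n_ignored_hotspots,
    sections = data.frame(file = files, first = sec$first, last = sec$last,
                          kind = sec$kind, boundary_pos = sec$boundary_pos)
  )
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

#' Load segmented haplotype data written by [save_segments()]
#'
#' @param dir run directory containing `manifest.json` and section files.
#' @return A list with `hm` (the reassembled [haplotype_matrix()]) and
#'   `plan` (the restored [segmentation_plan]).
#' @export
load_segments <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stopf("no manifest.json under %s", dir)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  sec <- man$sections
  mats <- vector("list", nrow(sec))
  pos <- vector("list", nrow(sec))
  vids <- vector("list", nrow(sec))
  sample_ids <- NULL
  for (k in seq_len(nrow(sec))) {
    lines <- readLines(file.path(dir, sec$file[k]))
    p <- as.numeric(strsplit(sub("^#positions=", "", lines[2]), ",")[[1]])
    hdr <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
    body <- strsplit(lines[-(1:3)], "\t", fixed = TRUE)
    sample_ids <- vapply(body, `[`, character(1), 1)
    dat <- do.call(rbind, lapply(body, function(x) as.integer(x[-1])))
    if (length(p) == 0) dat <- matrix(integer(), length(body), 0)
    mats[[k]] <- dat
    pos[[k]] <- p
    vids[[k]] <- hdr[-1]
  }
  plan <- new_segmentation_plan(
    data.frame(first = sec$first, last = sec$last, kind = sec$kind,
               boundary_pos = sec$boundary_pos),
    n_artificial = man$n_artificial,
    n_ignored_hotspots = man$n_ignored_hotspots,
    n_variants = man$n_variants)
  validate_plan(plan, man$n_variants)
  hm <- haplotype_matrix(do.call(cbind, mats), unlist(pos),
                         chrom = man$chrom, variant_ids = unlist(vids),
                         sample_ids = sample_ids)
  list(hm = hm, plan = plan)
}
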