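# VCF and sidecar-table I/O for haplotype matrices and genetic maps.

#' Read a phased VCF into a haplotype (or genotype) matrix
#'
#' Biallelic SNP records are kept; sites with more than \code{max_missing}
#' missing genotypes are dropped at load. In haplotype mode the phased GT
#' field \code{a|b} is split into two columns \code{<sample>_1} /
#' \code{<sample>_2} (unphased records are an error); in genotype mode
#' dosages 0/1/2 are returned per individual. Site functional classes
#' default to \code{"other"} and can be supplied via a sidecar table.
#'
#' @param path path to a VCF (v4.x, plain text or gzipped).
#' @param mode \code{"haplotype"} (default) or \code{"genotype"}.
#' @param classes optional sidecar: a data.frame or TSV path with columns
#'   \code{chrom}, \code{pos}, \code{class}.
#' @param max_missing per-site missing-genotype fraction above which the
#'   site is dropped (default 0.1, the phasing filter used upstream).
#' @return a [HaplotypeMatrix-class]
#' @export
readHaplotypeVcf <- function(path, mode = c("haplotype", "genotype"),
                             classes = NULL, max_missing = 0.1) {
  mode <- match.arg(mode)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (!all(bi)) {
    message(sprintf("dropping %d non-biallelic site(s)", sum(!bi)))
    v <- v[bi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.numeric(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      class = "other", stringsAsFactors = FALSE)
  info <- fix[, "INFO"]
  has_class <- !is.na(info) & grepl("CLASS=", info, fixed = TRUE)
  sites$class[has_class] <-
    sub(".*CLASS=([^;]+).*", "\\1", info[has_class])
  miss <- rowMeans(is.na(gt) | gt %in% c(".", "./.", ".|."))
  keep <- miss <= max_missing
  if (any(!keep))
    message(sprintf("dropping %d site(s) with > %.0f%% missing genotypes",
                    sum(!keep), 100 * max_missing))
  gt <- gt[keep, , drop = FALSE]
  sites <- sites[keep, , drop = FALSE]
  if (!is.null(classes)) {
    if (is.character(classes))
      classes <- read.table(classes, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    key <- paste(sites$chrom, sites$pos)
    m <- match(key, paste(classes$chrom, classes$pos))
    sites$class[!is.na(m)] <- classes$class[m[!is.na(m)]]
  }
  samples <- colnames(gt)
  if (mode == "haplotype") {
    if (any(grepl("/", gt, fixed = TRUE), na.rm = TRUE))
      stop("unphased genotypes found; haplotype mode requires phased GT (a|b)")
    split1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
    split2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
    geno <- matrix(NA_integer_, nrow(gt), 2L * ncol(gt))
    geno[, seq(1L, 2L * ncol(gt), by = 2L)] <- split1
    geno[, seq(2L, 2L * ncol(gt), by = 2L)] <- split2
    colnames(geno) <- as.vector(rbind(paste0(samples, "_1"),
                                      paste0(samples, "_2")))
  } else {
    a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
    a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
    geno <- matrix(a1 + a2, nrow(gt), ncol(gt),
                   dimnames = list(NULL, samples))
  }
  haplotypeMatrix(geno, sites, mode = mode)
}

#' Write a haplotype matrix as a phased VCF v4.2
#'
#' Haplotype columns \code{<individual>_1} / \code{<individual>_2} are
#' paired into one phased sample column each.
#'
#' @param hm a [HaplotypeMatrix-class] in haplotype mode.
#' @param path output path.
#' @return the path, invisibly
#' @export
writeHaplotypeVcf <- function(hm, path) {
  stopifnot(is(hm, "HaplotypeMatrix"), hm@mode == "haplotype")
  ids <- sub("_[12]$", "", colnames(hm@geno))
  inds <- unique(ids)
  if (!all(table(ids) == 2L))
    stop("haplotype columns must pair as <individual>_1 / <individual>_2")
  s <- hm@sites
  gtcols <- vapply(inds, function(i) {
    pair <- hm@geno[, ids == i, drop = FALSE]
    g <- paste(pair[, 1], pair[, 2], sep = "|")
    g[is.na(pair[, 1]) | is.na(pair[, 2])] <- ".|."
    g
  }, character(nrow(s)))
  gtcols <- matrix(gtcols, nrow = nrow(s))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", inds), collapse = "\t"))
  body <- apply(cbind(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS",
                      paste0("CLASS=", s$class), "GT", gtcols),
                1L, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genetic map from a TSV of anchors
#'
#' @param path TSV with header columns \code{chrom}, \code{pos}, \code{cm}.
#' @return a \code{"GeneticMap"} data.frame (see [geneticMap()])
#' @export
readGeneticMap <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  geneticMap(tab$chrom, tab$pos, tab$cm)
}

#' Write a genetic map as a TSV of anchors
#' @param map a \code{"GeneticMap"} data.frame.
#' @param path output path.
#' @return the path, invisibly
#' @export
writeGeneticMap <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
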