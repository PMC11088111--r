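#' Read an AllSites VCF
#'
#' Reads a VCF that retains invariant as well as variant sites ("AllSites"
#' dialect: invariant records have ALT ".") into an [allsites()] object.
#' Parsing is delegated to `VariantAnnotation::readVcf`; this wrapper converts
#' to 0-based coordinates, decodes GT strings, and extracts the GATK site
#' metrics used by [apply_filters()] when they are present.
#'
#' Half-called genotypes (e.g. `./1`) are treated as fully missing.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param samples optional character vector restricting to a sample subset;
#'   an error lists any requested sample absent from the file.
#' @return An [allsites()] object. Sites are returned in file order, which
#'   must be (chrom, pos) sorted.
#' @export
read_allsites_vcf <- function(path, samples = NULL) {
  if (!file.exists(path)) stop("no such VCF: ", path)
  hdr <- VariantAnnotation::scanVcfHeader(path)
  file_samples <- VariantAnnotation::samples(hdr)
  if (!is.null(samples)) {
    missing_s <- setdiff(samples, file_samples)
    if (length(missing_s))
      stop("samples absent from VCF: ", paste(missing_s, collapse = ", "))
    param <- VariantAnnotation::ScanVcfParam(samples = samples)
  } else {
    param <- VariantAnnotation::ScanVcfParam()
  }
  tryCatch({
  v <- suppressWarnings(VariantAnnotation::readVcf(path, param = param))
  gr <- SummarizedExperiment::rowRanges(v)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  pos0 <- GenomicRanges::start(gr) - 1L
  ref <- as.character(gr$REF)
  alt <- S4Vectors::unstrsplit(
    methods::as(gr$ALT, "CharacterList"), sep = ",")
  alt[is.na(alt)] <- ""
  # GATK writes spanning-deletion/'missing' ALT as "*" or "."; normalise
  alt[alt == "." | alt == "*"] <- ""

  gt <- VariantAnnotation::geno(v)$GT
  if (is.null(gt)) stop("VCF has no GT FORMAT field: ", path)
  dec <- decode_gt(gt)

  sl <- GenomeInfoDb::seqlengths(v)
  cl <- if (all(is.na(sl))) {
    agg <- tapply(pos0 + 1L, chrom, max)
    setNames(as.numeric(agg), names(agg))
  } else setNames(as.numeric(sl), names(sl))

  info_df <- NULL
  want <- intersect(c("FS", "MQRankSum", "MQ", "QD", "ReadPosRankSum", "SOR"),
                    rownames(VariantAnnotation::info(hdr)))
  if (length(want)) {
    iv <- VariantAnnotation::info(v)
    info_df <- as.data.frame(lapply(setNames(want, want), function(f)
      as.numeric(iv[[f]])))
  }

  g <- VariantAnnotation::geno(v)
  to_imat <- function(m) if (is.null(m)) NULL else {
    storage.mode(m) <- "integer"; unname(m)
  }
  allsites(chrom, pos0, ref, alt, dec$a1, dec$a2,
           samples = colnames(gt), contig_lengths = cl,
           gq = to_imat(g$GQ), dp = to_imat(g$DP), info = info_df)
  }, error = function(e) stop("malformed VCF '", path, "': ",
                              conditionMessage(e), call. = FALSE))
}

# Decode a character GT matrix ("0/1", ".|.", ...) into two integer allele
# matrices. Half-calls become fully missing.
decode_gt <- function(gt) {
  u <- unique(as.vector(gt))
  parts <- strsplit(u, "[/|]")
  a1u <- suppressWarnings(vapply(parts, function(p)
    if (length(p) >= 1) as.integer(sub("^\\.$", NA, p[1])) else NA_integer_,
    integer(1)))
  a2u <- suppressWarnings(vapply(parts, function(p)
    if (length(p) >= 2) as.integer(sub("^\\.$", NA, p[2])) else NA_integer_,
    integer(1)))
  half <- xor(is.na(a1u), is.na(a2u))
  a1u[half] <- NA_integer_; a2u[half] <- NA_integer_
  idx <- match(gt, u)
  d <- dim(gt)
  list(a1 = matrix(a1u[idx], d[1], d[2]),
       a2 = matrix(a2u[idx], d[1], d[2]))
}

#' Write an allsites object as an AllSites VCF
#'
#' Emits VCF 4.2 text with invariant records carrying ALT ".", FORMAT
#' `GT[:GQ:DP]`, and any INFO metrics stored on the object. Together with
#' [read_allsites_vcf()] this round-trips genotypes, missingness and INFO.
#'
#' @param x an [allsites()] object.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_allsites_vcf <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  h <- c("##fileformat=VCFv4.2",
         sprintf("##contig=<ID=%s,length=%d>", names(x$contig_lengths),
                 as.integer(x$contig_lengths)))
  if (!is.null(x$info))
    h <- c(h, sprintf(
      "##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
      names(x$info), names(x$info)))
  h <- c(h, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  fmt <- "GT"
  if (!is.null(x$gq)) {
    h <- c(h, "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">")
    fmt <- paste0(fmt, ":GQ")
  }
  if (!is.null(x$dp)) {
    h <- c(h, "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
    fmt <- paste0(fmt, ":DP")
  }
  h <- c(h, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", x$samples), collapse = "\t"))
  writeLines(h, con)

  S <- length(x$pos0)
  if (S == 0L) return(invisible(path))
  gts <- matrix(paste0(ifelse(is.na(x$gt1), ".", x$gt1), "/",
                       ifelse(is.na(x$gt2), ".", x$gt2)),
                nrow = S)
  if (!is.null(x$gq))
    gts <- matrix(paste0(gts, ":", ifelse(is.na(x$gq), ".", x$gq)), nrow = S)
  if (!is.null(x$dp))
    gts <- matrix(paste0(gts, ":", ifelse(is.na(x$dp), ".", x$dp)), nrow = S)
  info_s <- if (is.null(x$info)) rep(".", S) else {
    cols <- lapply(names(x$info), function(f) {
      v <- x$info[[f]]
      ifelse(is.na(v), NA_character_, paste0(f, "=", format(v, trim = TRUE)))
    })
    s <- apply(do.call(cbind, cols), 1L, function(r)
      paste(r[!is.na(r)], collapse = ";"))
    ifelse(s == "", ".", s)
  }
  body <- paste(x$chrom, x$pos0 + 1L, ".", x$ref,
                ifelse(x$alt == "", ".", x$alt), ".", ".", info_s, fmt,
                sep = "\t")
  body <- paste(body, apply(gts, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read a sample-to-population map
#'
#' @param path two-column TSV: sample id, population label.
#' @param header logical; does the file carry a header row?
#' @return A named character vector (sample -> population) of class
#'   `popmap`, with per-population sample lists in attribute `pops`.
#' @export
read_population_map <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("no such population map: ", path)
  if (file.size(path) == 0L) stop("empty population map: ", path)
  dt <- fread(path, header = header, sep = "\t",
              colClasses = "character")
  if (nrow(dt) == 0L) stop("empty population map: ", path)
  if (ncol(dt) < 2L) stop("population map must have two columns")
  population_map(dt[[1]], dt[[2]])
}

#' Construct a population map from vectors
#' @param sample_id character vector of sample ids.
#' @param population character vector of population labels, same length.
#' @return A `popmap` object (see [read_population_map()]).
#' @export
population_map <- function(sample_id, population) {
  stopifnot(length(sample_id) == length(population))
  dup <- sample_id[duplicated(sample_id)]
  if (length(dup))
    stop("duplicated sample id(s) in population map: ",
         paste(unique(dup), collapse = ", "))
  pm <- setNames(as.character(population), as.character(sample_id))
  structure(pm, pops = split(names(pm), unname(pm)), class = "popmap")
}

#' @export
print.popmap <- function(x, ...) {
  pops <- attr(x, "pops")
  cat(sprintf("<popmap> %d samples in %d population(s): %s\n",
              length(x), length(pops),
              paste(sprintf("%s (n=%d)", names(pops), lengths(pops)),
                    collapse = ", ")))
  invisible(x)
}
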