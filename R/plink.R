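# PLINK1 binary triplet (bed/bim/fam), SNP-major layout. Two bits per call:
# 00 = hom A1 (dosage 2), 01 = missing, 10 = het, 11 = hom A2 (dosage 0).

plink_prefix <- function(path) sub("\\.(bed|bim|fam)$", "", path)

read_genotypes_plink <- function(path, ploidy_mode) {
  prefix <- plink_prefix(path)
  bim <- utils::read.table(paste0(prefix, ".bim"), header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos", "a1", "a2"))
  fam <- utils::read.table(paste0(prefix, ".fam"), header = FALSE,
                           stringsAsFactors = FALSE)
  n <- nrow(fam)
  p <- nrow(bim)
  raw <- readBin(paste0(prefix, ".bed"), "raw",
                 n = 3 + p * ceiling(n / 4))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK .bed file", call. = FALSE)
  }
  if (raw[3] != as.raw(0x01)) {
    stop("only SNP-major .bed files are supported", call. = FALSE)
  }
  bytes_per_snp <- ceiling(n / 4)
  body <- as.integer(raw[-(1:3)])
  if (length(body) != p * bytes_per_snp) {
    stop("truncated .bed file", call. = FALSE)
  }
  # unpack 2-bit codes: 4 calls per byte, low bits first
  codes <- matrix(0L, nrow = 4 * bytes_per_snp, ncol = p)
  bm <- matrix(body, nrow = bytes_per_snp, ncol = p)
  for (k in 0:3) {
    codes[seq(k + 1, 4 * bytes_per_snp, by = 4), ] <- bm %% 4L
    bm <- bm %/% 4L
  }
  codes <- codes[seq_len(n), , drop = FALSE]
  dose <- matrix(NA_real_, n, p)
  dose[codes == 0L] <- 2   # hom A1
  dose[codes == 2L] <- 1   # het
  dose[codes == 3L] <- 0   # hom A2
  rownames(dose) <- as.character(fam[[2]])
  colnames(dose) <- bim$id
  if (ploidy_mode == "inbred") dose[dose == 1] <- NA
  dose <- orient_minor(dose)
  genotype_matrix(dose, chrom = bim$chrom, pos_bp = bim$pos,
                  ploidy_mode = ploidy_mode)
}

write_plink <- function(geno, prefix) {
  prefix <- plink_prefix(prefix)
  v <- geno$values
  ok <- is.na(v) | v %in% c(0, 1, 2)
  if (!all(ok)) {
    stop("PLINK writer requires dosages in {0, 1, 2, NA}; ",
         "fractional (imputed) dosages cannot be written", call. = FALSE)
  }
  n <- nrow(v)
  p <- ncol(v)
  bim <- data.frame(chrom = geno$chrom, id = colnames(v), cm = 0,
                    pos = geno$pos_bp, a1 = "A", a2 = "B")
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = rownames(v), iid = rownames(v), pat = 0, mat = 0,
                    sex = 0, phe = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  codes <- matrix(1L, n, p)  # missing
  codes[!is.na(v) & v == 2] <- 0L
  codes[!is.na(v) & v == 1] <- 2L
  codes[!is.na(v) & v == 0] <- 3L
  bytes_per_snp <- ceiling(n / 4)
  pad <- 4 * bytes_per_snp - n
  if (pad > 0) codes <- rbind(codes, matrix(0L, pad, p))
  weights <- c(1L, 4L, 16L, 64L)
  bytes <- matrix(0L, bytes_per_snp, p)
  for (k in 1:4) {
    bytes <- bytes + weights[k] * codes[seq(k, 4 * bytes_per_snp, by = 4), ,
                                        drop = FALSE]
  }
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(prefix)
}
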