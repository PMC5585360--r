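#' Two-lead annotated ECG record
#'
#' Container for a two-lead ECG signal with beat annotations, the unit of
#' input for the whole pipeline. Sample indices are 0-based throughout, so an
#' annotation at index `i` refers to `lead_a[i + 1]` in R's 1-based vectors.
#'
#' @param lead_a,lead_b Numeric amplitude series in millivolts; equal length.
#' @param fs Sampling rate in Hz (MIT-BIH records use 360).
#' @param beats Data frame with columns `sample` (0-based integer index of the
#'   R point, strictly increasing, within the signal) and `symbol` (single
#'   beat annotation character).
#' @param record_id Record identifier string.
#' @return An object of class `ecg_record`.
#' @examples
#' r <- ecg_record(sin(1:720 / 20), cos(1:720 / 20), fs = 360,
#'                 beats = data.frame(sample = c(100L, 400L),
#'                                    symbol = c("N", "V")))
#' r
#' @export
ecg_record <- function(lead_a, lead_b, fs, beats, record_id = "rec") {
  lead_a <- as.numeric(lead_a)
  lead_b <- as.numeric(lead_b)
  if (length(lead_a) != length(lead_b))
    stop("lead_a and lead_b must have equal length (got ",
         length(lead_a), " and ", length(lead_b), ")")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(beats)) beats <- data.frame(sample = integer(), symbol = character())
  if (!all(c("sample", "symbol") %in% names(beats)))
    stop("beats must have columns 'sample' and 'symbol'")
  beats <- data.frame(sample = as.integer(beats$sample),
                      symbol = as.character(beats$symbol),
                      stringsAsFactors = FALSE)
  if (nrow(beats)) {
    if (any(diff(beats$sample) <= 0))
      stop("beat sample indices must be strictly increasing")
    if (any(beats$sample < 0L) || any(beats$sample >= length(lead_a)))
      stop("beat sample index out of signal bounds: ",
           paste(beats$sample[beats$sample < 0L | beats$sample >= length(lead_a)],
                 collapse = ", "))
  }
  structure(list(record_id = as.character(record_id), fs = fs,
                 lead_a = lead_a, lead_b = lead_b, beats = beats),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ecg_record '%s': %d samples x 2 leads @ %g Hz (%.1f s), %d beats\n",
              x$record_id, length(x$lead_a), x$fs,
              length(x$lead_a) / x$fs, nrow(x$beats)))
  if (nrow(x$beats)) {
    tab <- table(x$beats$symbol)
    cat("  symbols:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' @param x An `ecg_record`.
#' @param seconds Time span to draw, from the record start.
#' @param ... Passed to [graphics::plot()].
#' @rdname ecg_record
#' @export
plot.ecg_record <- function(x, seconds = 5, ...) {
  n <- min(length(x$lead_a), round(seconds * x$fs))
  tt <- (seq_len(n) - 1L) / x$fs
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (lead in c("lead_a", "lead_b")) {
    graphics::plot(tt, x[[lead]][seq_len(n)], type = "l",
                   xlab = "time (s)", ylab = paste(lead, "(mV)"),
                   main = if (lead == "lead_a") x$record_id else "", ...)
    b <- x$beats[x$beats$sample < n, ]
    if (nrow(b)) {
      graphics::abline(v = b$sample / x$fs, col = "grey70", lty = 3)
      graphics::mtext(b$symbol, at = b$sample / x$fs, side = 3,
                      line = -1, cex = 0.7)
    }
  }
  invisible(x)
}

# ---- AAMI superclass mapping -------------------------------------------------

#' Map MIT-BIH beat annotation symbols to AAMI superclasses
#'
#' The five AAMI superclasses are N (normal and bundle-branch block beats),
#' S (supraventricular ectopic), V (ventricular ectopic), F (fusion of
#' ventricular and normal) and Q (paced/unknown). The default table is the
#' standard one used in inter-patient evaluation studies; pass `table` to
#' override it.
#'
#' @param symbol Character vector of beat annotation symbols.
#' @param table Named character vector mapping symbols to superclasses.
#' @return Character vector with values in `{"N","S","V","F","Q"}`.
#' @examples
#' aami_superclass(c("L", "A", "E"))
#' @export
aami_superclass <- function(symbol, table = aami_symbol_table()) {
  out <- unname(table[as.character(symbol)])
  if (anyNA(out)) {
    bad <- unique(symbol[is.na(out)])
    stop("unknown beat annotation symbol(s): ", paste(bad, collapse = ", "),
         " (non-beat annotations must be filtered out first)")
  }
  out
}

#' @rdname aami_superclass
#' @export
aami_symbol_table <- function() {
  c(N = "N", L = "N", R = "N", e = "N", j = "N",
    A = "S", a = "S", J = "S", S = "S",
    V = "V", E = "V",
    F = "F",
    "/" = "Q", f = "Q", Q = "Q")
}

#' @rdname aami_superclass
#' @export
aami_classes <- function() c("N", "S", "V", "F", "Q")

# ---- inter-patient partitions ------------------------------------------------

.partitions <- list(
  DS1  = c("101", "106", "108", "109", "112", "114", "115", "116", "118",
           "119", "122", "124", "201", "203", "205", "207", "208", "209",
           "215", "220", "223", "230"),
  DS11 = c("101", "106", "108", "109", "114", "115", "116", "119", "122",
           "209", "223"),
  DS12 = c("112", "118", "124", "201", "203", "205", "207", "208", "215",
           "220", "230"),
  DS2  = c("100", "103", "105", "111", "113", "117", "121", "123", "200",
           "202", "210", "212", "213", "214", "219", "221", "222", "228",
           "231", "232", "233", "234")
)

#' MIT-BIH inter-patient record partitions
#'
#' Record identifiers of the canonical inter-patient split: DS1 (training) and
#' DS2 (evaluation), with DS1 further divided into DS11 (optimization
#' training) and DS12 (optimization validation) so that every patient's beats
#' stay on one side of each split. The four paced records (102, 104, 107, 217)
#' are excluded.
#'
#' @param name One of `"DS1"`, `"DS11"`, `"DS12"`, `"DS2"`.
#' @return Character vector of record identifiers.
#' @export
ecg_partition <- function(name) {
  name <- match.arg(name, names(.partitions))
  .partitions[[name]]
}

# ---- published DS2 confusion matrix -----------------------------------------

#' Published DS2 confusion matrix (common filter)
#'
#' The 3-class confusion matrix reported for the method's final DS2 evaluation
#' under the common (low-pass + high-pass) preprocessing chain, with true
#' classes in rows and predicted classes in columns, ordered N, S, V. Useful
#' as direct input to [aami_metrics()].
#'
#' @return Integer matrix with dimnames `list(true, predicted)`.
#' @examples
#' aami_metrics(published_confusion())
#' @export
published_confusion <- function() {
  m <- matrix(c(41043L, 792L, 1834L,
                657L, 1111L, 125L,
                200L, 195L, 2724L),
              nrow = 3, byrow = TRUE,
              dimnames = list(true = c("N", "S", "V"),
                              predicted = c("N", "S", "V")))
  m
}

# ---- CSV dialect -------------------------------------------------------------

# CSV dialect: <base>.csv holds "# record_id=<id> fs=<hz>" then header
# sample,lead_a_mV,lead_b_mV; <base>.ann.csv holds header sample,symbol.

read_ecg_csv <- function(path) {
  sig_path <- paste0(path, ".csv")
  ann_path <- paste0(path, ".ann.csv")
  if (!file.exists(sig_path)) stop("signal file not found: ", sig_path)
  if (!file.exists(ann_path)) stop("annotation file not found: ", ann_path)
  hdr <- readLines(sig_path, n = 1L)
  if (!grepl("^#", hdr))
    stop("malformed CSV record: first line of ", sig_path,
         " must be a '# record_id=... fs=...' comment, got: ", hdr)
  rid <- sub(".*record_id=(\\S+).*", "\\1", hdr)
  fs <- suppressWarnings(as.numeric(sub(".*fs=(\\S+).*", "\\1", hdr)))
  if (is.na(fs)) stop("malformed CSV header (fs missing): ", hdr)
  sig <- utils::read.csv(sig_path, comment.char = "#")
  need <- c("sample", "lead_a_mV", "lead_b_mV")
  if (!all(need %in% names(sig)))
    stop("signal CSV must have columns ", paste(need, collapse = ", "),
         "; got ", paste(names(sig), collapse = ", "))
  ann <- utils::read.csv(ann_path, colClasses = c("integer", "character"))
  if (!all(c("sample", "symbol") %in% names(ann)))
    stop("annotation CSV must have columns sample, symbol")
  ecg_record(sig$lead_a_mV, sig$lead_b_mV, fs = fs,
             beats = ann, record_id = rid)
}

write_ecg_csv <- function(record, path) {
  sig_path <- paste0(path, ".csv")
  ann_path <- paste0(path, ".ann.csv")
  con <- file(sig_path, "w")
  on.exit(close(con))
  writeLines(sprintf("# record_id=%s fs=%.10g", record$record_id, record$fs), con)
  utils::write.csv(data.frame(sample = seq_along(record$lead_a) - 1L,
                              lead_a_mV = record$lead_a,
                              lead_b_mV = record$lead_b),
                   con, row.names = FALSE, quote = FALSE)
  utils::write.csv(record$beats, ann_path, row.names = FALSE, quote = FALSE)
  invisible(c(sig_path, ann_path))
}

# ---- WFDB dialect (format 212, MIT annotation files) ------------------------

# Standard MIT annotation type codes (subset covering beat annotations).
.atr_codes <- c(N = 1L, L = 2L, R = 3L, a = 4L, V = 5L, F = 6L, J = 7L,
                A = 8L, S = 9L, E = 10L, j = 11L, "/" = 12L, Q = 13L,
                e = 34L, n = 35L, f = 38L)

.atr_symbols <- {
  s <- names(.atr_codes)
  names(s) <- as.character(.atr_codes)
  s
}

read_ecg_wfdb <- function(path) {
  hea_path <- paste0(path, ".hea")
  if (!file.exists(hea_path)) stop("header file not found: ", hea_path)
  lines <- readLines(hea_path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 4L)
    stop("malformed WFDB header line: ", lines[1])
  rid <- sub("/.*", "", top[1])
  nsig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  nsamp <- as.integer(top[4])
  if (is.na(nsig) || is.na(fs) || is.na(nsamp))
    stop("malformed WFDB header line: ", lines[1])
  if (nsig != 2L)
    stop("unsupported record: expected 2 signals, header declares ", nsig)
  sig <- lapply(lines[2:3], function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < 3L) stop("malformed WFDB signal line: ", l)
    if (sub("x.*", "", f[2]) != "212")
      stop("unsupported WFDB format '", f[2], "' (only 212 is supported)")
    gain_field <- f[3]
    baseline <- 0
    if (grepl("\\(", gain_field))
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_field))
    gain <- as.numeric(sub("[(/].*", "", gain_field))
    if (is.na(gain) || gain == 0) gain <- 200
    list(file = f[1], gain = gain, baseline = baseline)
  })
  dat_path <- file.path(dirname(hea_path), sig[[1]]$file)
  raw <- readBin(dat_path, "raw", n = file.size(dat_path))
  adc <- decode_212(raw, 2L * nsamp)
  a <- (adc[seq(1L, by = 2L, length.out = nsamp)] - sig[[1]]$baseline) / sig[[1]]$gain
  b <- (adc[seq(2L, by = 2L, length.out = nsamp)] - sig[[2]]$baseline) / sig[[2]]$gain
  atr_path <- paste0(path, ".atr")
  beats <- if (file.exists(atr_path)) read_atr(atr_path) else
    data.frame(sample = integer(), symbol = character())
  ecg_record(a, b, fs = fs, beats = beats, record_id = rid)
}

write_ecg_wfdb <- function(record, path, gain = 200, adc_zero = 0L) {
  rid <- record$record_id
  nsamp <- length(record$lead_a)
  dat_file <- paste0(basename(path), ".dat")
  adc_a <- as.integer(round(record$lead_a * gain)) + adc_zero
  adc_b <- as.integer(round(record$lead_b * gain)) + adc_zero
  if (any(abs(c(adc_a, adc_b) - adc_zero) > 2047L))
    stop("signal exceeds the 12-bit range of format 212 at gain ", gain)
  inter <- integer(2L * nsamp)
  inter[seq(1L, by = 2L, length.out = nsamp)] <- adc_a
  inter[seq(2L, by = 2L, length.out = nsamp)] <- adc_b
  writeBin(encode_212(inter), paste0(path, ".dat"))
  hea <- c(sprintf("%s 2 %.10g %d", rid, record$fs, nsamp),
           sprintf("%s 212 %g(%d) 12 %d 0 0 0 lead_a", dat_file, gain, adc_zero, adc_zero),
           sprintf("%s 212 %g(%d) 12 %d 0 0 0 lead_b", dat_file, gain, adc_zero, adc_zero))
  writeLines(hea, paste0(path, ".hea"))
  write_atr(record$beats, paste0(path, ".atr"))
  invisible(paste0(path, c(".hea", ".dat", ".atr")))
}

decode_212 <- function(raw, n) {
  nb <- length(raw)
  npairs <- nb %/% 3L
  v <- as.integer(raw)
  b0 <- v[seq(1L, by = 3L, length.out = npairs)]
  b1 <- v[seq(2L, by = 3L, length.out = npairs)]
  b2 <- v[seq(3L, by = 3L, length.out = npairs)]
  s1 <- b0 + bitwShiftL(bitwAnd(b1, 0x0FL), 8L)
  s2 <- b2 + bitwShiftL(bitwShiftR(b1, 4L), 8L)
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  out <- integer(2L * npairs)
  out[seq(1L, by = 2L, length.out = npairs)] <- s1
  out[seq(2L, by = 2L, length.out = npairs)] <- s2
  out[seq_len(n)]
}

encode_212 <- function(samples) {
  if (length(samples) %% 2L) samples <- c(samples, 0L)
  s <- ifelse(samples < 0L, samples + 4096L, samples)
  s1 <- s[seq(1L, length(s), by = 2L)]
  s2 <- s[seq(2L, length(s), by = 2L)]
  b0 <- bitwAnd(s1, 0xFFL)
  b1 <- bitwOr(bitwShiftL(bitwShiftR(s2, 8L), 4L), bitwShiftR(s1, 8L))
  b2 <- bitwAnd(s2, 0xFFL)
  out <- integer(3L * length(s1))
  out[seq(1L, by = 3L, length.out = length(s1))] <- b0
  out[seq(2L, by = 3L, length.out = length(s1))] <- b1
  out[seq(3L, by = 3L, length.out = length(s1))] <- b2
  as.raw(out)
}

# MIT annotation format: 2-byte little-endian words; type = high 6 bits of the
# second byte, time increment = remaining 10 bits. SKIP (59) carries a 4-byte
# absolute increment; NUM/SUB/CHN/AUX are modifier words we skip; 0 terminates.
read_atr <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  v <- as.integer(raw)
  i <- 1L
  t <- 0L
  samp <- integer()
  sym <- character()
  while (i + 1L <= length(v)) {
    lo <- v[i]; hi <- v[i + 1L]
    code <- bitwShiftR(hi, 2L)
    incr <- bitwOr(bitwShiftL(bitwAnd(hi, 0x03L), 8L), lo)
    i <- i + 2L
    if (code == 0L && incr == 0L) break
    if (code == 59L) {          # SKIP: next 4 bytes are the increment
      if (i + 3L > length(v)) stop("truncated SKIP word in ", path)
      big <- bitwOr(bitwShiftL(v[i + 1L], 8L), v[i]) * 65536L +
        bitwOr(bitwShiftL(v[i + 3L], 8L), v[i + 2L])
      t <- t + big
      i <- i + 4L
    } else if (code %in% c(60L, 61L, 62L)) {
      next                      # NUM / SUB / CHN modifiers: no time advance
    } else if (code == 63L) {   # AUX: incr = byte count, padded to even
      i <- i + incr + (incr %% 2L)
    } else {
      t <- t + incr
      s <- .atr_symbols[as.character(code)]
      if (!is.na(s)) {          # unknown/non-beat types advance time only
        samp <- c(samp, t)
        sym <- c(sym, s)
      }
    }
  }
  data.frame(sample = samp, symbol = sym, stringsAsFactors = FALSE)
}

write_atr <- function(beats, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  prev <- 0L
  for (k in seq_len(nrow(beats))) {
    code <- .atr_codes[beats$symbol[k]]
    if (is.na(code))
      stop("cannot encode annotation symbol '", beats$symbol[k], "'")
    incr <- beats$sample[k] - prev
    if (incr > 1023L) {
      writeBin(as.raw(c(0L, bitwShiftL(59L, 2L))), con)
      hi16 <- incr %/% 65536L
      lo16 <- incr %% 65536L
      writeBin(as.raw(c(hi16 %% 256L, hi16 %/% 256L,
                        lo16 %% 256L, lo16 %/% 256L)), con)
      incr <- 0L
    }
    writeBin(as.raw(c(bitwAnd(incr, 0xFFL),
                      bitwOr(bitwShiftL(code, 2L), bitwShiftR(incr, 8L)))), con)
    prev <- beats$sample[k]
  }
  writeBin(as.raw(c(0L, 0L)), con)
  invisible(path)
}

# ---- dispatching front end ---------------------------------------------------

#' Read or write a two-lead ECG record
#'
#' `read_ecg()` loads a record from disk in either the WFDB dialect
#' (`<path>.hea` / `.dat` in format 212, plus `<path>.atr` annotations) or the
#' CSV dialect (`<path>.csv` signal file with a `# record_id=... fs=...`
#' comment line, plus `<path>.ann.csv` annotations). `write_ecg()` is its
#' inverse; a write followed by a read reproduces the record (amplitudes in
#' the WFDB dialect are quantized to the ADC gain).
#'
#' @param path Base path without extension.
#' @param dialect `"wfdb"` or `"csv"`.
#' @param record An `ecg_record`.
#' @param ... Passed to the dialect writer (`gain`, `adc_zero` for WFDB).
#' @return `read_ecg()` returns an [ecg_record]; `write_ecg()` the file paths.
#' @export
read_ecg <- function(path, dialect = c("wfdb", "csv")) {
  dialect <- match.arg(dialect)
  switch(dialect, wfdb = read_ecg_wfdb(path), csv = read_ecg_csv(path))
}

#' @rdname read_ecg
#' @export
write_ecg <- function(record, path, dialect = c("wfdb", "csv"), ...) {
  stopifnot(inherits(record, "ecg_record"))
  dialect <- match.arg(dialect)
  switch(dialect, wfdb = write_ecg_wfdb(record, path, ...),
         csv = write_ecg_csv(record, path))
}
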