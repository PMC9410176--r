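# Minimal WFDB record support: format 16 (16-bit little-endian two's
# complement, interleaved samples), single .dat file per record. Covers the
# conventional `.hea` fields gain(baseline)/units; physical value =
# (digital - baseline) / gain, gain in adu/mV.

read_wfdb <- function(path) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop("file not found: ", hea)
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  rec <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  nsig <- as.integer(rec[2])
  fs <- as.numeric(rec[3])
  nsamp <- as.integer(rec[4])
  if (is.na(fs) || is.na(nsig)) stop("unsupported format dialect: bad header")
  sig <- lines[2:(1 + nsig)]
  dat_files <- character(nsig); gains <- numeric(nsig)
  baselines <- numeric(nsig); leads <- character(nsig)
  for (i in seq_len(nsig)) {
    f <- strsplit(trimws(sig[i]), "[[:space:]]+")[[1]]
    dat_files[i] <- f[1]
    if (f[2] != "16") stop("unsupported format dialect: only format 16 is supported")
    spec <- f[3]
    gains[i] <- as.numeric(sub("^([0-9.eE+-]+).*$", "\\1", spec))
    baselines[i] <- if (grepl("\\(", spec)) {
      as.numeric(sub("^.*\\(([0-9-]+)\\).*$", "\\1", spec))
    } else 0
    leads[i] <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ")
                else paste0("sig", i)
  }
  if (length(unique(dat_files)) != 1) {
    stop("unsupported format dialect: multi-file records not supported")
  }
  dat <- file.path(dirname(hea), dat_files[1])
  if (!file.exists(dat)) stop("file not found: ", dat)
  raw <- readBin(dat, what = "integer", size = 2, signed = TRUE,
                 endian = "little", n = nsig * nsamp)
  if (length(raw) < nsig * nsamp) stop("truncated .dat file")
  m <- matrix(raw, nrow = nsig)  # interleaved: column = one time sample
  phys <- (m - baselines) / gains
  ecg_record(t(phys), leads, fs = fs,
             subject_id = sub("\\.hea$", "", basename(hea)))
}

write_wfdb <- function(record, path, gain = 1000) {
  base <- sub("\\.hea$", "", path)
  name <- basename(base)
  m <- record$samples  # samples x leads, mV
  digital <- round(m * gain)
  if (any(abs(digital) > 32767)) {
    stop("amplitude exceeds 16-bit range at gain ", gain)
  }
  hea <- c(
    sprintf("%s %d %g %d", name, ncol(m), record$fs, nrow(m)),
    sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s",
            name, gain, as.integer(digital[1, ]), colnames(m))
  )
  writeLines(hea, paste0(base, ".hea"))
  con <- file(paste0(base, ".dat"), "wb")
  on.exit(close(con))
  # interleave: sample-major order
  writeBin(as.integer(t(digital)), con, size = 2, endian = "little")
  invisible(base)
}
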