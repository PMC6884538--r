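#' Write a subject's volumes as NIfTI with JSON sidecars
#'
#' Each condition volume becomes one `.nii.gz` plus a `.json` sidecar
#' carrying the acquisition metadata that DICOM private tags would hold on
#' a scanner (volume type, saturation power and offset, or TR and flip
#' angle). ROI masks are written as NIfTI label volumes.
#'
#' @param dataset Output of [generate_subject_dataset()].
#' @param dir Output directory (created if needed).
#' @param subject_id Identifier used as the filename prefix.
#' @return `dir`, invisibly.
#' @export
write_subject_dataset <- function(dataset, dir, subject_id = "subj") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  protocol <- dataset$protocol
  np <- length(protocol$powers_deg)
  write1 <- function(vol, stem, meta) {
    RNifti::writeNifti(vol, file.path(dir, paste0(stem, ".nii.gz")))
    jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  for (k in seq_len(protocol$n_conditions)) {
    pi_ <- (k - 1) %% np + 1
    oi <- (k - 1) %/% np + 1
    stem <- sprintf("%s_mt_%03d", subject_id, k)
    write1(dataset$mt_stack[, , , k], stem,
           list(type = "mt", power_deg = protocol$powers_deg[pi_],
                offset_khz = protocol$offsets_khz[oi]))
  }
  if (!is.null(dataset$vtr_stack)) {
    for (k in seq_along(dataset$vtr$vtr_trs_ms)) {
      write1(dataset$vtr_stack[, , , k], sprintf("%s_vtr_%d", subject_id, k),
             list(type = "vtr", tr_ms = dataset$vtr$vtr_trs_ms[k],
                  fa_deg = dataset$vtr$fa_deg))
    }
  }
  if (!is.null(dataset$afi_stack)) {
    for (k in 1:2) {
      write1(dataset$afi_stack[, , , k], sprintf("%s_afi_%d", subject_id, k),
             list(type = "afi", tr_ms = dataset$vtr$afi_trs_ms[k],
                  fa_deg = dataset$vtr$fa_deg))
    }
  }
  for (tendon in c("att", "ptt")) {
    m <- dataset[[paste0(tendon, "_mask")]]$mask
    RNifti::writeNifti(array(as.numeric(m), dim(m)),
                       file.path(dir, sprintf("%s_mask_%s.nii.gz",
                                              subject_id, tendon)))
  }
  invisible(dir)
}

#' Read a volume series from a directory of NIfTI + sidecar files
#'
#' Scans `dir` for `<prefix>_*.nii.gz` volumes with `.json` sidecars and
#' reassembles the MT, VTR and AFI stacks. All volumes must share one
#' shape; MT conditions are ordered on the protocol grid (power fastest)
#' and any condition missing from the series is reported by name.
#'
#' @param dir Directory written by [write_subject_dataset()].
#' @param subject_id Filename prefix.
#' @param protocol The [mt_protocol] the MT series must cover.
#' @return List with `mt_stack`, `vtr_stack`, `afi_stack`, `vtr_trs_ms`,
#'   `afi_trs_ms`, `att_mask`, `ptt_mask` (masks `NULL` when absent).
#' @export
read_volume_series <- function(dir, subject_id, protocol) {
  files <- list.files(dir, pattern = paste0("^", subject_id,
                                            "_.*\\.nii(\\.gz)?$"),
                      full.names = TRUE)
  if (!length(files)) stop("no volumes found under ", dir)
  shape <- NULL
  recs <- list()
  for (f in files) {
    stem <- sub("\\.nii(\\.gz)?$", "", f)
    side <- paste0(stem, ".json")
    if (!file.exists(side)) next  # masks and unannotated volumes
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    vol <- as.array(RNifti::readNifti(f))
    if (length(dim(vol)) == 2) dim(vol) <- c(dim(vol), 1)  # squeezed slice
    if (is.null(shape)) shape <- dim(vol)
    if (!all(dim(vol) == shape)) {
      stop("shape mismatch in ", basename(f), ": got ",
           paste(dim(vol), collapse = "x"), ", expected ",
           paste(shape, collapse = "x"))
    }
    recs[[length(recs) + 1]] <- list(vol = vol, meta = meta)
  }
  types <- vapply(recs, function(r) r$meta$type, character(1))

  np <- length(protocol$powers_deg)
  mt_recs <- recs[types == "mt"]
  key <- function(p, o) sprintf("%g_%g", p, o)
  have <- vapply(mt_recs, function(r) key(r$meta$power_deg,
                                          r$meta$offset_khz), character(1))
  grid <- expand.grid(power = protocol$powers_deg,
                      offset = protocol$offsets_khz)
  want <- key(grid$power, grid$offset)
  missing <- setdiff(want, have)
  if (length(missing)) {
    pretty <- vapply(strsplit(missing, "_"), function(x) {
      sprintf("(%s deg, %s kHz)", x[1], x[2])
    }, character(1))
    stop("MT series is missing conditions: ", paste(pretty, collapse = ", "))
  }
  mt <- array(0, c(shape, length(want)))
  for (k in seq_along(want)) {
    mt[, , , k] <- mt_recs[[match(want[k], have)]]$vol
  }

  grab_series <- function(type) {
    rs <- recs[types == type]
    if (!length(rs)) return(NULL)
    trs <- vapply(rs, function(r) r$meta$tr_ms, numeric(1))
    rs <- rs[order(trs)]
    st <- array(0, c(shape, length(rs)))
    for (k in seq_along(rs)) st[, , , k] <- rs[[k]]$vol
    list(stack = st, trs_ms = sort(trs))
  }
  vtr <- grab_series("vtr")
  afi <- grab_series("afi")

  read_mask <- function(tendon) {
    f <- file.path(dir, sprintf("%s_mask_%s.nii.gz", subject_id, tendon))
    if (!file.exists(f)) return(NULL)
    arr <- as.array(RNifti::readNifti(f)) > 0.5
    if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1)
    roi_mask(arr, toupper(tendon))
  }

  list(mt_stack = mt,
       vtr_stack = if (!is.null(vtr)) vtr$stack,
       afi_stack = if (!is.null(afi)) afi$stack,
       vtr_trs_ms = if (!is.null(vtr)) vtr$trs_ms,
       afi_trs_ms = if (!is.null(afi)) afi$trs_ms,
       att_mask = read_mask("att"), ptt_mask = read_mask("ptt"))
}

#' Write or read a cohort table as CSV
#'
#' Tables carry provenance as `#`-prefixed header comments: the generating
#' seed and a hash of the generating configuration.
#'
#' @param table A cohort table (see [validate_cohort_table()]) or any
#'   data.frame.
#' @param path File path.
#' @param seed,config Optional provenance: the seed and any serializable
#'   configuration object (hashed into the header).
#' @return `write_cohort_table` returns `path` invisibly;
#'   `read_cohort_table` returns the data.frame with attributes `seed` and
#'   `config_hash` when present.
#' @export
write_cohort_table <- function(table, path, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(paste0("# seed: ", seed), con)
  if (!is.null(config)) {
    h <- sum(utf8ToInt(jsonlite::toJSON(config, auto_unbox = TRUE,
                                        digits = 10)) *
               (seq_along(utf8ToInt(jsonlite::toJSON(config,
                                                     auto_unbox = TRUE,
                                                     digits = 10))) %% 97 + 1))
    writeLines(paste0("# config_hash: ", format(h)), con)
  }
  utils::write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  header <- readLines(path, n = 5)
  tab <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  seed_line <- grep("^# seed:", header, value = TRUE)
  hash_line <- grep("^# config_hash:", header, value = TRUE)
  if (length(seed_line)) {
    attr(tab, "seed") <- as.integer(sub("^# seed: *", "", seed_line[1]))
  }
  if (length(hash_line)) {
    attr(tab, "config_hash") <- sub("^# config_hash: *", "", hash_line[1])
  }
  tab
}
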