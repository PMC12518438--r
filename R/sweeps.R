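#' Family of voltage- or current-clamp sweeps
#'
#' @param sweeps List of data frames with columns `time_s` and `signal`
#'   (pA for voltage clamp, mV for current clamp), one per protocol entry.
#' @param protocol Data frame describing the commanded protocol, one row per
#'   sweep. Required column: `v_pip_mv` (commanded pipette potential of the
#'   test pulse). Optional columns depending on `kind`: `pulse_start_s`,
#'   `pulse_end_s`, and for two-pulse recovery protocols `interval_s`,
#'   `pulse2_start_s`, `pulse2_end_s`.
#' @param kind Protocol kind: `"iv"`, `"inactivation"`, `"recovery"` or
#'   `"ik1"`.
#' @param capacitance_pF Cell capacitance in pF (measured, not estimated).
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, protocol, kind, capacitance_pF) {
  stopifnot(is.list(sweeps), is.data.frame(protocol))
  abort_if(length(sweeps) != nrow(protocol),
           "protocol rows (%d) must align 1:1 with sweeps (%d)",
           nrow(protocol), length(sweeps))
  abort_if(!"v_pip_mv" %in% names(protocol), "protocol needs v_pip_mv")
  abort_if(!is.numeric(capacitance_pF) || capacitance_pF <= 0,
           "capacitance_pF must be positive")
  for (s in sweeps) {
    stopifnot(is.data.frame(s), all(c("time_s", "signal") %in% names(s)))
    dt <- diff(s$time_s)
    abort_if(any(dt <= 0) ||
               max(abs(dt - stats::median(dt))) > 1e-6 * stats::median(dt),
             "sweep sampling must be uniform and increasing")
  }
  structure(list(sweeps = sweeps, protocol = protocol, kind = kind,
                 capacitance_pF = capacitance_pF),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %s protocol, %d sweeps, C = %.1f pF\n",
              x$kind, length(x$sweeps), x$capacitance_pF))
  invisible(x)
}

#' Write a sweep set to delimited text plus protocol YAML
#'
#' One tab-separated file per sweep (`<stem>_sweep<k>.tsv`) and a
#' `<stem>_protocol.yaml` holding the protocol table, kind and capacitance.
#'
#' @param ss A [sweep_set()].
#' @param stem Output path stem.
#' @return `stem`, invisibly.
#' @export
write_sweeps <- function(ss, stem) {
  stopifnot(inherits(ss, "sweep_set"))
  for (k in seq_along(ss$sweeps)) {
    utils::write.table(ss$sweeps[[k]], sprintf("%s_sweep%03d.tsv", stem, k),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  yaml::write_yaml(list(kind = ss$kind,
                        capacitance_pF = ss$capacitance_pF,
                        n_sweeps = length(ss$sweeps),
                        protocol = lapply(seq_len(nrow(ss$protocol)),
                                          function(i) as.list(ss$protocol[i, , drop = FALSE]))),
                   paste0(stem, "_protocol.yaml"))
  invisible(stem)
}

#' Read a sweep set written by [write_sweeps()]
#'
#' @param stem Path stem used at write time.
#' @return A [sweep_set()].
#' @export
read_sweeps <- function(stem) {
  meta_path <- paste0(stem, "_protocol.yaml")
  abort_if(!file.exists(meta_path), "protocol file '%s' missing", meta_path)
  meta <- yaml::read_yaml(meta_path)
  prot <- do.call(rbind, lapply(meta$protocol, function(r) as.data.frame(r)))
  sweeps <- lapply(seq_len(meta$n_sweeps), function(k) {
    utils::read.table(sprintf("%s_sweep%03d.tsv", stem, k),
                      header = TRUE, sep = "\t")
  })
  sweep_set(sweeps, prot, meta$kind, meta$capacitance_pF)
}
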