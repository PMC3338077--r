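# Build a long-format feature table from per-probe matrices.
# signal/error: probe x sample matrices with dimnames; negctrl/ctrl flag
# probes by rowname.
make_feature_table <- function(signal, error, negctrl = character(0),
                               control = character(0)) {
  probes <- rownames(signal)
  samples <- colnames(signal)
  data.frame(
    sample_id = rep(samples, each = length(probes)),
    probe_id = rep(probes, times = length(samples)),
    total_gene_signal = as.vector(signal),
    total_gene_error = as.vector(error),
    is_control_probe = rep(probes %in% c(control, negctrl), length(samples)),
    is_negative_control = rep(probes %in% negctrl, length(samples)),
    stringsAsFactors = FALSE
  )
}

# A small detection matrix with named rows/columns from a 0/1 template.
make_detections <- function(template) {
  stopifnot(is.matrix(template))
  mode(template) <- "logical"
  template
}

# Shared cytoband reference (loading parses a 30 KB table; cache per session).
cached_ref <- local({
  ref <- NULL
  function() {
    if (is.null(ref)) ref <<- load_cytoband_reference()
    ref
  }
})
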