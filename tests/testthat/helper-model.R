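# Shared fixtures: the canonical model is built once per test run; small toy
# graphs and mechanism sets are constructed programmatically.

canonical_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- pc_model()
    m
  }
})

# A passive unbranched cable as a pc_graph-compatible object.
toy_chain <- function(n = 1, len = 20, diam = 20, ra = 120, cm = 1,
                      region = "soma") {
  seg_area <- pi * diam * len
  ra_link <- cylinder_axial_resistance(len, diam, ra)
  comps <- data.frame(
    id = seq_len(n), section_id = "sec", seg = seq_len(n),
    pos = (seq_len(n) - 0.5) / n,
    parent = c(0L, seq_len(n - 1)),
    ra = c(NA, rep(ra_link, n - 1)),
    area = seg_area, len = len, diam = diam, cm = cm,
    region = region, branch_id = NA_integer_, limb_id = NA_integer_,
    dist_soma = (seq_len(n) - 1) * len)
  g <- list(comps = comps, sections = NULL, n = n,
            branch_index = list(), connection_segment = integer(),
            soma = 1L, passive = list(ra = ra))
  class(g) <- "pc_graph"
  g
}

# Leak-only mechanism set on a toy graph.
toy_leak_mech <- function(graph, g_leak = 1e-4, e_leak = -65) {
  ch <- list(leak_soma = channel_spec("leak_soma", erev = e_leak))
  mechanism_set(graph, ch,
                densities = list(soma = c(leak_soma = g_leak)),
                capool = calcium_pool())
}

# Coarse but honest threshold measurement used by slower tests.
quick_threshold <- function(model, branch_id = 8, hold = 0, ffi = NULL,
                            trials = 4, ns = seq(20, 70, 5), seed = 1,
                            mech = model$mech) {
  io <- run_io_curve(model, branch_id, ns, trials, hold, seed, ffi = ffi,
                     mech = mech)
  io
}
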