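# Shared fixtures, built once per test run.

fixture_trace <- local({
  tr <- NULL
  function() {
    if (is.null(tr))
      tr <<- generate_trace(sim_condition(1, 10, 1, snr = 4,
                                          trace_length_s = 5), seed = 7)
    tr
  }
})

# a tiny gradient-check configuration (64-sample windows)
tiny_cfg <- function(path_id = 1)
  bnet_config(path_id, window_len_samples = 64, base_width = 8,
              kernel1 = 7, stride1 = 2, head_hidden = 6)

get_leaf <- function(l, path) Reduce(`[[`, path, l)

assign_leaf <- function(l, path, val) {
  if (length(path) == 1) { l[[path[1]]] <- val; return(l) }
  l[[path[1]]] <- assign_leaf(l[[path[1]]], path[-1], val)
  l
}
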