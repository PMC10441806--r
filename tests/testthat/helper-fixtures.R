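# small shared fixtures; everything is generated in code under fixed seeds

fast_dirt_config <- function(...) {
  dirt_config(n_nt = 300, ...)
}

# tiny non-spatial network reused across eifnet/analysis tests
tiny_net <- local({
  cache <- new.env()
  function(scale = 0.05, seed = 101) {
    key <- paste0("s", scale, "_", seed)
    if (is.null(cache[[key]])) {
      params <- scale_network_params(network_params("nonspatial"), scale)
      cache[[key]] <- list(params = params,
                           conn = build_nonspatial(params, seed = seed))
    }
    cache[[key]]
  }
})
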