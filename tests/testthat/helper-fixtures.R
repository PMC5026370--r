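# Scaled-down versions of the two packaged experimental designs, shared by
# the acceptance tests: two protein concentrations and an 8-point ligand
# grid preserve the mechanism-discriminating features (minimum, asymmetry,
# both concentration regimes) at a fraction of the full 3 x 16 cost.
# Built lazily and cached for the session.
.fixture_cache <- new.env(parent = emptyenv())

scaled_design_table <- function(figure) {
  key <- paste0(figure, "_scaled")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  P0 <- if (figure == "fig2") c(0.5, 1.5) else c(1, 3)
  curves <- make_fixture(figure, seed = 1L, P0 = P0, n_L0 = 8L)
  tab <- fit_kobs_table(curves, N_max = 5L, seed = 1L)
  res <- list(curves = curves, table = tab,
              scheme = attr(curves, "scheme"))
  .fixture_cache[[key]] <- res
  res
}
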