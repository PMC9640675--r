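# Shared in-code fixtures: tiny grids and hand-built uniform ocean states.

tiny_grid <- function(res_lat = 30, res_lon = 30) generate_grid(res_lat, res_lon)

# an ocean_state with spatially uniform fields, built by hand (not via the
# generator) so projection tests have closed-form expectations
uniform_state <- function(nf = 1, r_tr = 0.5, ph = 7.81, po4 = 0.05,
                          dop = 0.075, aux = list(fe = 0.5, n = 0.8),
                          era = "2081-2100", grid = tiny_grid()) {
  shape <- dim(grid$cell_area)
  m <- function(v) matrix(v, shape[1], shape[2])
  gf <- function(name, units, v) gridded_field(name, units, m(v), era)
  structure(
    list(era = era, grid = grid,
         ph_t = gf("ph_t", "pH (total scale)", ph),
         po4 = gf("po4", "mmol m-3", po4),
         dop = gf("dop", "mmol m-3", dop),
         nf = gf("nf", "g N m-2 yr-1", nf),
         r_tr = gf("r_tr", "1", r_tr),
         aux_limits = lapply(aux, function(a) gf("aux", "1", a))),
    class = "ocean_state")
}

all_true_mask <- function(grid) matrix(TRUE, nrow(grid$cell_area), ncol(grid$cell_area))
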