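# Inclusion-sphere grid cavity volumes.

test_that("sphere recipes resolve to the centroid of the named atoms", {
  atom <- data.frame(serial = 1:3, elety = "CZ", resid = "PHE",
                     chain = "A", resno = c(69, 121, 199), elesy = "C",
                     vdw = 1.7, stringsAsFactors = FALSE)
  coords <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0))
  topo <- upoflex:::.new_md_structure(atom, coords)
  s <- resolve_sphere(sphere_recipe(c(69, 121, 199), "CZ", 4), coords, topo)
  expect_equal(s$center, c(1, 1, 0))
  expect_equal(s$radius, 4)
  # two atoms at +/-2 -> origin
  s2 <- resolve_sphere(sphere_recipe(c(69, 121), "CZ"),
                       rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 0, 9)), topo)
  expect_equal(s2$center, c(0, 0, 0))
  # missing atom names the variant convention
  expect_error(resolve_sphere(sphere_recipe(69, "CD1"), coords, topo),
               "Ala: CB, Leu: CD1, Phe: CZ")
})

test_that("mutated channel-mouth anchors use the residue's own atom", {
  ref <- synth_reference(50, seed = 1,
                         sidechain_atoms = c("10" = "CZ", "20" = "CD1"))
  expect_equal(mouth_reference_atom(c("PHE", "LEU", "ALA")),
               c("CZ", "CD1", "CB"))
  expect_error(mouth_reference_atom("GLY"), "no channel-mouth reference")
  # a Phe-like and a Leu-like anchor both resolve on the fixture
  r_phe <- sphere_recipe(10, mouth_reference_atom("PHE"))
  r_leu <- sphere_recipe(20, mouth_reference_atom("LEU"))
  expect_s3_class(resolve_sphere(r_phe, ref$xyz, ref), "inclusion_sphere")
  expect_s3_class(resolve_sphere(r_leu, ref$xyz, ref), "inclusion_sphere")
  # asking the pre-mutation atom of a mutated residue fails
  expect_error(resolve_sphere(sphere_recipe(20, "CZ"), ref$xyz, ref),
               "not found in residue 20")
})

empty_topo <- function() {
  atom <- data.frame(serial = 1L, elety = "C", resid = "SHL", chain = "A",
                     resno = 1L, elesy = "C", vdw = 1.7,
                     stringsAsFactors = FALSE)
  upoflex:::.new_md_structure(atom, matrix(c(999, 999, 999), 1, 3))
}

test_that("an empty inclusion sphere recovers the analytic volume", {
  topo <- empty_topo()  # single far-away atom, cannot clash
  v <- frame_cavity_volume(topo$xyz, topo, inclusion_sphere(c(0, 0, 0), 4),
                           grid_spacing = 0.5)
  expect_equal(v, 4 / 3 * pi * 4^3, tolerance = 0.02)
})

test_that("halving the grid spacing changes the volume by < 1%", {
  topo <- empty_topo()
  s <- inclusion_sphere(c(0, 0, 0), 4)
  v1 <- frame_cavity_volume(topo$xyz, topo, s, grid_spacing = 0.5)
  v2 <- frame_cavity_volume(topo$xyz, topo, s, grid_spacing = 0.25)
  expect_lt(abs(v2 / v1 - 1), 0.01)
})

test_that("a fully occluding atom zeroes the volume", {
  atom <- data.frame(serial = 1L, elety = "X", resid = "BIG", chain = "A",
                     resno = 1L, elesy = "C", vdw = 5,
                     stringsAsFactors = FALSE)
  topo <- upoflex:::.new_md_structure(atom, matrix(0, 1, 3))
  v <- frame_cavity_volume(topo$xyz, topo, inclusion_sphere(c(0, 0, 0), 4),
                           grid_spacing = 0.5)
  expect_equal(v, 0)
})

test_that("disjoint spheres add; coincident spheres do not double count", {
  topo <- empty_topo()
  s1 <- inclusion_sphere(c(0, 0, 0), 4)
  s2 <- inclusion_sphere(c(20, 0, 0), 4)
  v_pair <- frame_cavity_volume(topo$xyz, topo, list(s1, s2),
                                grid_spacing = 0.5)
  expect_equal(v_pair, 2 * 4 / 3 * pi * 64, tolerance = 0.02)
  v_same <- frame_cavity_volume(topo$xyz, topo, list(s1, s1),
                                grid_spacing = 0.5)
  expect_equal(v_same, 4 / 3 * pi * 64, tolerance = 0.02)
})

test_that("shell phantom leaves the void volume intact", {
  ph <- synth_cavity_phantom(phantom_spec(void_radius = 4,
                                          shell_radius = 6), n_frames = 1)
  v <- frame_cavity_volume(frame_coords(ph, 1), ph$topology,
                           inclusion_sphere(c(0, 0, 0), 4),
                           grid_spacing = 0.5)
  expect_equal(v, 4 / 3 * pi * 64, tolerance = 0.02)
})

test_that("volume is monotone in probe_pad and added atoms", {
  ph <- synth_cavity_phantom(phantom_spec(void_radius = 4,
                                          shell_radius = 6), n_frames = 1)
  m <- frame_coords(ph, 1); topo <- ph$topology
  s <- inclusion_sphere(c(0, 0, 0), 4)
  pads <- c(0, 0.5, 1.1, 2)
  vols <- vapply(pads, function(p)
    frame_cavity_volume(m, topo, s, grid_spacing = 0.5, probe_pad = p),
    numeric(1))
  expect_true(all(diff(vols) <= 0))
  # adding an atom inside the void can only remove volume
  atom2 <- rbind(topo$atom,
                 data.frame(serial = nrow(topo$atom) + 1, elety = "C",
                            resid = "SHL", chain = "A",
                            resno = nrow(topo$atom) + 1, elesy = "C",
                            vdw = 1.7))
  topo2 <- upoflex:::.new_md_structure(atom2, rbind(m, c(2, 0, 0)))
  v0 <- frame_cavity_volume(m, topo, s, grid_spacing = 0.5)
  v1 <- frame_cavity_volume(rbind(m, c(2, 0, 0)), topo2, s,
                            grid_spacing = 0.5)
  expect_lt(v1, v0)
})

test_that("volume is invariant under a rigid transform of the system", {
  ph <- synth_cavity_phantom(phantom_spec(), n_frames = 1)
  m <- frame_coords(ph, 1); topo <- ph$topology
  recipe <- sphere_recipe(c(1, 2), "C", 4)  # antipodal anchors -> center
  s <- resolve_sphere(recipe, m, topo)
  v0 <- frame_cavity_volume(m, topo, s, grid_spacing = 0.5)
  th <- 0.6
  r <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  m2 <- m %*% t(r) + matrix(c(7.3, -2.1, 4.9), nrow(m), 3, byrow = TRUE)
  s2 <- resolve_sphere(recipe, m2, topo)
  v2 <- frame_cavity_volume(m2, topo, s2, grid_spacing = 0.5)
  expect_equal(v2, v0, tolerance = 0.03)
})

test_that("contiguity keeps only the component connected to the centers", {
  # wall of atoms at x = 6 splits a 2-sphere dumbbell; seed sphere at origin
  wall <- as.matrix(expand.grid(x = 6, y = seq(-8, 8, 0.8),
                                z = seq(-8, 8, 0.8)))
  atom <- data.frame(serial = seq_len(nrow(wall)), elety = "C",
                     resid = "WAL", chain = "A",
                     resno = seq_len(nrow(wall)), elesy = "C", vdw = 1.2,
                     stringsAsFactors = FALSE)
  topo <- upoflex:::.new_md_structure(atom, wall)
  spheres <- list(inclusion_sphere(c(0, 0, 0), 4),
                  inclusion_sphere(c(12, 0, 0), 4))
  v_all <- frame_cavity_volume(wall, topo, spheres, grid_spacing = 0.5)
  v_conn <- frame_cavity_volume(wall, topo,
                                list(inclusion_sphere(c(0, 0, 0), 4)),
                                grid_spacing = 0.5, contiguity = TRUE)
  # without contiguity both lobes count; connected-only keeps one lobe
  expect_gt(v_all, 1.8 * v_conn)
  expect_equal(v_conn, 4 / 3 * pi * 64, tolerance = 0.02)
  # with seeds in both lobes the flood fill keeps both
  v_conn2 <- frame_cavity_volume(wall, topo, spheres, grid_spacing = 0.5,
                                 contiguity = TRUE)
  expect_equal(v_conn2, v_all, tolerance = 1e-9)
  # occluded seed warns and returns zero
  big <- upoflex:::.new_md_structure(
    data.frame(serial = 1L, elety = "X", resid = "BIG", chain = "A",
               resno = 1L, elesy = "C", vdw = 5, stringsAsFactors = FALSE),
    matrix(0, 1, 3))
  expect_warning(
    v0 <- frame_cavity_volume(big$xyz, big,
                              inclusion_sphere(c(0, 0, 0), 4),
                              grid_spacing = 0.5, contiguity = TRUE),
    "occluded")
  expect_equal(v0, 0)
})

test_that("volume_series: static constancy, breathing, last-frame identity", {
  spec <- phantom_spec(void_radius = 4, shell_radius = 6)
  ph <- synth_cavity_phantom(spec, n_frames = 5)
  recipe <- sphere_recipe(c(1, 2), "C", 4)
  vs <- volume_series(ph, recipe, last_n_frames = 5, grid_spacing = 0.5)
  expect_equal(length(unique(round(vs$volume_A3, 6))), 1)

  # breathing: shell radius 6 +/- 1 over a 40-ps period, sampled densely
  bspec <- phantom_spec(void_radius = 4, shell_radius = 6,
                        breathing = list(amplitude_A = 1, period_ps = 40))
  phb <- synth_cavity_phantom(bspec, n_frames = 41, frame_interval_ps = 1)
  vsb <- volume_series(phb, recipe, last_n_frames = 41, grid_spacing = 0.5)
  # at max expansion the full inclusion sphere is void; at max contraction
  # the clash surface clips it at shell - vdw
  expect_equal(max(vsb$volume_A3),
               phantom_expected_volume(bspec, shell_radius = 7),
               tolerance = 0.03)
  expect_equal(min(vsb$volume_A3),
               phantom_expected_volume(bspec, shell_radius = 5),
               tolerance = 0.03)

  v_last <- volume_series(ph, recipe, last_n_frames = 1,
                          grid_spacing = 0.5)
  expect_equal(v_last$volume_A3,
               frame_cavity_volume(frame_coords(ph, 5), ph$topology,
                                   resolve_sphere(recipe,
                                                  frame_coords(ph, 5),
                                                  ph$topology),
                                   grid_spacing = 0.5))
  expect_error(volume_series(ph, recipe, last_n_frames = 9), "1..5")
})
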