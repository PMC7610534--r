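test_that("lipids per vesicle counts both leaflets", {
  # 4*pi*(89.5^2 + 85.5^2) / 0.71 nm^2
  expect_equal(lipids_per_vesicle(179, 4, 71),
               4 * pi * (89.5^2 + 85.5^2) / 0.71, tolerance = 1e-12)
  expect_equal(lipids_per_vesicle(179, 4, 71), 2.712e5, tolerance = 1e-3)
  # h = 0: two coincident leaflets
  expect_equal(lipids_per_vesicle(100, 0, 71), 8 * pi * 50^2 / 0.71,
               tolerance = 1e-12)
  # doubling the area per lipid halves the count
  expect_equal(lipids_per_vesicle(179, 4, 142),
               lipids_per_vesicle(179, 4, 71) / 2, tolerance = 1e-12)
  expect_error(lipids_per_vesicle(7, 4), "geometry")
})

test_that("liposome concentration reproduces the published value", {
  n <- liposomes_per_ml(preparation_spec(), lipid_spec("DOPC/POPC"))
  expect_equal(n, 7.18e9, tolerance = 1e-3)
  # linear in lipid mass
  expect_equal(
    liposomes_per_ml(preparation_spec(lipid_mass_concentration = 5)),
    2 * n, tolerance = 1e-12)
  expect_equal(
    liposomes_per_ml(preparation_spec(lipid_mass_concentration = 1e-30)),
    0, tolerance = 1e-20)
  # the dimensional reading of the same equation is exactly 1000x higher
  expect_equal(liposomes_per_ml(convention = "dimensional"), 1000 * n,
               tolerance = 1e-12)
  # inversely proportional to the lipids per vesicle: doubling the area per
  # lipid halves N_tot and doubles the vesicle count
  n2 <- liposomes_per_ml(preparation_spec(),
                         lipid_spec("DOPC/POPC", area_per_lipid = 142))
  expect_equal(n2, 2 * n, tolerance = 1e-12)
})

test_that("first-principles SI rebuild matches liposomes_per_ml", {
  prep <- preparation_spec()
  lip <- lipid_spec("DOPC/POPC")
  ntot <- 4 * pi * ((179 / 2)^2 + (179 / 2 - 4)^2) / (71 / 100)
  mol_per_ml <- prep$lipid_mass_concentration / lip$molar_mass / 1000
  expect_lt(abs(liposomes_per_ml(prep, lip, "dimensional") -
                mol_per_ml * 6.02214e23 / ntot) /
            liposomes_per_ml(prep, lip, "dimensional"), 1e-12)
})

test_that("calcein vesicle counting uses the lumen volume", {
  prep <- preparation_spec()
  # 50 mM in a 171 nm lumen: 0.050 * pi * 171^3 / 6 * 1e-24 L
  per_vesicle <- 0.050 * pi * 171^3 / 6 * 1e-24
  expect_equal(per_vesicle, 1.309e-19, tolerance = 1e-3)
  expect_equal(vesicles_from_calcein(per_vesicle, prep), 1, tolerance = 1e-12)
  expect_equal(vesicles_from_calcein(0, prep), 0)
  expect_equal(vesicles_from_calcein(1.309e-12, prep), 1.0e7,
               tolerance = 1e-3)
  expect_error(
    vesicles_from_calcein(1e-12, preparation_spec(vesicle_diameter = 8,
                                                  bilayer_thickness = 4)),
    "lumen")
})

test_that("area ratios reproduce the printed size-regime values", {
  expect_equal(area_ratio(179, 5), (179 / 5)^2, tolerance = 1e-12)
  expect_equal(signif(area_ratio(179, 5), 2), 1300)
  expect_equal(signif(area_ratio(179, 10), 2), 320)
  expect_equal(signif(area_ratio(179, 25), 2), 51)
  expect_equal(signif(area_ratio(179, 60), 2), 8.9)
  expect_equal(area_ratio(179, 179), 1)
  # reciprocal identity on a grid
  for (d in c(1, 5, 60, 500))
    expect_equal(area_ratio(179, d) * area_ratio(d, 179), 1,
                 tolerance = 1e-12)
  expect_error(area_ratio(179, 0), "positive")
})

test_that("nanoparticle surface area per mL matches supplier stocks", {
  expect_equal(np_surface_area_per_ml(nanoparticle_spec(5, 4.76e13)),
               4.76e13 * pi * (5e-9)^2, tolerance = 1e-12)
  expect_equal(np_surface_area_per_ml(nanoparticle_spec(5, 4.76e13)),
               3.74e-3, tolerance = 1e-3)
  expect_equal(np_surface_area_per_ml(nanoparticle_spec(10, 6.40e12)),
               2.01e-3, tolerance = 2e-3)
  expect_equal(np_surface_area_per_ml(nanoparticle_spec(10, 0)), 0)
})

test_that("liposome surface area routes agree up to the leaflet geometry", {
  prep <- preparation_spec()
  lip <- lipid_spec("DOPC/POPC")
  count_route <- liposome_surface_area_per_ml(prep, lip, "count")
  expect_equal(count_route, 7.18e9 * pi * (179e-9)^2, tolerance = 1e-3)
  expect_equal(count_route, 7.23e-4, tolerance = 2e-3)
  # the leaflet route equals the mean of outer and inner leaflet areas:
  # ratio (1 + ((D-2h)/D)^2) / 2, about 4.4% below the outer-area route
  leaflet <- liposome_surface_area_per_ml(prep, lip, "leaflet")
  geom <- (1 + (171 / 179)^2) / 2
  expect_equal(leaflet / count_route, geom, tolerance = 1e-6)
  expect_lt(abs(leaflet - count_route) / count_route, 0.05)
  # convention factor cancels in the route ratio
  l2 <- liposome_surface_area_per_ml(prep, lip, "leaflet", "dimensional")
  c2 <- liposome_surface_area_per_ml(prep, lip, "count", "dimensional")
  expect_equal(l2 / c2, geom, tolerance = 1e-6)
  expect_equal(
    liposome_surface_area_per_ml(preparation_spec(lipid_mass_concentration = 1e-30),
                                 lip), 0, tolerance = 1e-25)
})

test_that("supplier stock table round-trips through the bundled fixture", {
  path <- system.file("extdata", "aunp_stocks.csv", package = "npwrap")
  tab <- read_table(path, "populations")
  expect_equal(tab, aunp_stocks(), ignore_attr = TRUE)
})
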