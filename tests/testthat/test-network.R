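test_that("population census matches the microcircuit table", {
  net <- reference_network()
  cnt <- population_counts(net)
  n <- setNames(cnt$N, cnt$name)
  expect_equal(n[["1L2/3E"]], 10341)
  expect_equal(n[["1L4I"]], 2739)
  expect_equal(n[["1L5E"]], 2425)
  expect_equal(n[["2L6I"]], 1474)
  expect_equal(sum(n[startsWith(names(n), "1")]), 38582)
  expect_identical(n[1:8], setNames(n[9:16], names(n[1:8])))
})

test_that("default network instantiates all table pathways plus two inter-column", {
  net <- build_network(0.3, 0.02)
  expect_equal(nrow(net$populations), 16)
  # 55 nonzero intra-column entries per column + 2 inter-column pathways
  expect_equal(nrow(net$pathways), 2 * 55 + 2)
  p <- dplyr::filter(net$pathways, source == "1L5I", target == "1L5E")
  expect_equal(p$P, 0.3765)
  expect_equal(p$g_peak, 2.672e-2)
  inter <- dplyr::filter(net$pathways, source == "1L2/3E", target == "2L2/3I")
  expect_equal(inter$P, 0.1)
  expect_equal(inter$g_peak, 3.276e-3)
  # no other cross-column coupling
  col_of <- function(x) substr(x, 1, 1)
  cross <- dplyr::filter(net$pathways,
                         col_of(source) != col_of(target))
  expect_equal(sort(paste(cross$source, cross$target)),
               c("1L2/3E 2L2/3I", "2L2/3E 1L2/3I"))
})

test_that("structural perturbations zero the right probabilities and nothing else", {
  base <- build_network(0.3, 0.02)
  blocked <- build_network(0.3, 0.02, perturbation = "block_L6E_to_L4I")
  changed <- dplyr::anti_join(blocked$pathways, base$pathways,
                              by = c("source", "target", "P", "g_peak"))
  expect_equal(sort(changed$source), c("1L6E", "2L6E"))
  expect_equal(sort(changed$target), c("1L4I", "2L4I"))
  expect_equal(changed$P, c(0, 0))
  was <- dplyr::filter(base$pathways, source == "1L6E", target == "1L4I")
  expect_equal(was$P, 0.1057)

  no6 <- build_network(0.3, 0.02, perturbation = "remove_layer6")
  expect_equal(nrow(no6$populations), 16) # populations never deleted
  l6 <- grepl("L6", no6$pathways$source) | grepl("L6", no6$pathways$target)
  expect_true(all(no6$pathways$P[l6] == 0))
  expect_identical(no6$pathways$P[!l6], base$pathways$P[!l6])

  blockE <- build_network(0.3, 0.02, perturbation = "block_L6E_to_L4E")
  pE <- dplyr::filter(blockE$pathways, source == "2L6E", target == "2L4E")
  expect_equal(pE$P, 0)
})

test_that("the pathway set is symmetric under column exchange", {
  net <- build_network(0.3, 0.02)
  swap <- function(x) chartr("12", "21", substr(x, 1, 1)) |>
    paste0(substring(x, 2))
  swapped <- net$pathways |>
    dplyr::mutate(source = swap(source), target = swap(target)) |>
    dplyr::arrange(source, target)
  expect_equal(dplyr::arrange(net$pathways, source, target), swapped)
})

test_that("background-current centers keep the 1 : 0.8 E : I ratio", {
  net <- build_network(0.25, 0.03)
  pops <- net$populations
  expect_equal(unique(pops$I_back_center[pops$cell_class == "I"]) /
                 unique(pops$I_back_center[pops$cell_class == "E"]), 0.8)
  expect_equal(unique(pops$I_back_width[pops$cell_class == "E"]), 0.25)
  expect_equal(unique(pops$I_back_width[pops$cell_class == "I"]), 0.03)
})

test_that("table overrides apply and invalid overrides are rejected", {
  net <- build_network(0.3, 0.02,
                       overrides = list(counts = c("L5E" = 1000),
                                        p_intra = list("L5I->L5E" = 0.5)))
  expect_equal(population_counts(net)$N[population_counts(net)$name == "2L5E"],
               1000)
  expect_equal(dplyr::filter(net$pathways, source == "1L5I",
                             target == "1L5E")$P, 0.5)
  expect_error(build_network(0.3, 0.02, overrides = list(counts = c(L9X = 5))),
               class = "columnet_config_error")
  expect_error(build_network(0.3, 0.02,
                             overrides = list(p_intra = list("L5I->L5E" = -1))),
               class = "columnet_config_error")
  expect_error(build_network(-0.1, 0.02), class = "columnet_config_error")
})

test_that("network configuration round-trips through YAML", {
  for (pert in c("none", "remove_layer6", "block_L6E_to_L4E")) {
    net <- build_network(0.46, 0.045, perturbation = pert)
    path <- withr::local_tempfile(fileext = ".yaml")
    network_config(net, path)
    back <- read_network_config(path)
    expect_equal(back$populations, net$populations)
    expect_equal(back$pathways, net$pathways)
    expect_equal(back$perturbation, net$perturbation)
    expect_equal(back$delta_e, net$delta_e)
    expect_equal(back$delta_i, net$delta_i)
  }
})
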