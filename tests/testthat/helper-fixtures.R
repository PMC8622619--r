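# Shared fixtures, built once per test run (the catalog replay takes a few
# seconds of alignment time).

.fx <- new.env(parent = emptyenv())

fixture_cfg <- function() {
  if (is.null(.fx$cfg)) .fx$cfg <- sim_config(seed = 42L)
  .fx$cfg
}

fixture_model <- function() {
  if (is.null(.fx$model)) .fx$model <- simulate_reference(fixture_cfg())
  .fx$model
}

fixture_panel <- function() {
  if (is.null(.fx$panel)) .fx$panel <- simulate_panel(fixture_model(), fixture_cfg())
  .fx$panel
}

fixture_calls <- function() {
  if (is.null(.fx$calls)) {
    .fx$calls <- call_panel(fixture_model(), fixture_panel()$sequences)
  }
  .fx$calls
}

# allele label of a haplotype row, looked up through the truth table
fixture_allele_of <- function(haplotype_row) {
  truth <- fixture_panel()$truth
  truth$allele[truth$accession == haplotype_row$accessions[[1]][1]][1]
}

# one representative sequence per catalog allele
fixture_seq_for <- function(allele) {
  pan <- fixture_panel()
  pan$sequences[[which(pan$truth$allele == allele)[1]]]
}

# the full-form printed variant names of the replayed catalog (genomic names
# carry the contig prefix)
catalog_printed_names <- function() {
  list(
    coding = c("c.126_134del", "c.495G>T", "c.528G>C", "c.530C>G", "c.729C>G"),
    utr = c("c.-140A>G", "c.-102_-91del", "c.*8C>T", "c.*285A>G", "c.*312A>T"),
    intron = c("c.325+32_325+33insTCC", "c.325+169G>C", "c.326-39A>G",
               "c.326-174A>G", "c.689+136A>G", "c.689+241T>C"),
    genomic = c("chr2A:g.687048627G>C", "chr2A:g.687048382C>T",
                "chr2A:g.687048137G>T", "chr2A:g.687048328A>G",
                "chr2A:g.687052487C>T", "chr2A:g.687052487_687052488del")
  )
}
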