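# Fixtures are built in code: a tiny hand-written dataset covering
# perfect matches, a mismatch duplex and missing fields, plus helpers
# for random sequences.

toy_csv_lines <- function() {
  c("seq1,seq2,duplex_id,struct1,struct2,dg_exp,dg_err,ds_exp,ds_err,dh_exp,dh_err,temperature,conc_self,conc_nonself,na_conc",
    "AAAA,TTTT,toy1,((((,)))),-2.0,,,,,,25,,1e-4,1",
    "GCGC,GCGC,toy2,((((,)))),-5.5,0.1,n.r.,,-40.2,,37,5e-6,,1",
    # one G:T mismatch at position 2 of seq1
    "ACGT,ATGT,toy3,(.((,)).),-1.1,,,,,,25,,1e-4,0.1",
    "ATATATAT,ATATATAT,toy4,((((((((,)))))))),-3.9,,,,,,37,1e-4,,1")
}

write_toy_csv <- function(path = tempfile(fileext = ".csv"),
                          lines = toy_csv_lines()) {
  writeLines(lines, path)
  path
}

toy_dataset <- function() read_duplex_dataset(write_toy_csv())

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
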