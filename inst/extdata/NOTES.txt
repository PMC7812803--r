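Reference in vivo anchor values used by the synthetic-data generators and
tests. All three tables transcribe published flow-cytometry / sequencing
summary statistics from the study this model emulates:

  day7_census.tsv     Day-7 splenic census of the cMyc+ GC B cell
                      subpopulations (mean +/- SEM cells per spleen).
                      The lateCD23lo subpopulation count was not printed
                      (printed = FALSE, values NA); downstream calibration
                      derives it from the compartment shares.
  ctv_composition.tsv Percentage of each cMyc+ subpopulation among cMyc+
                      GC B cells per CellTrace division compartment
                      (div4-div6), 70 h after transfer. The prePB rows were
                      described only qualitatively ("similar percentage
                      across divisions") and are flagged printed = FALSE.
  clone_mutations.tsv Unmutated / total sequenced IgG1+ clones in the
                      cMyc+early subpopulation for three independent sorts
                      (pooled unmutated fraction 14/162 = 8.6%).
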