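Place copies of the original study's deposited data files here to enable the
deposited-data checks (they are not redistributable with the package):

  body_measurements.csv    per-specimen linear measurements (376 specimens):
                           columns species, specimen_id (optional), body_weight,
                           body_length, wing_length, tail_length, tarsus_length,
                           culmen_length, altitude (optional); use the col_map
                           argument of read_measurements() if the deposited
                           header names differ
  aligned_coordinates.txt  aligned beak landmark coordinates, one specimen per
                           row, columns x1 y1 ... x21 y21 (306 specimens)
  phylogeny.tre            rooted 14-taxon Newick tree with branch lengths

Load with paridmorph::read_deposited_study(<this directory>).
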