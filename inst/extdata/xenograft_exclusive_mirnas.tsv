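mirna_id
hsa-miR-1224-5p
hsa-miR-126*
hsa-miR-1290
hsa-miR-1300
hsa-miR-135a*
hsa-miR-142-3p
hsa-miR-144
hsa-miR-150
hsa-miR-150*
hsa-miR-181c*
hsa-miR-548c-5p
hsa-miR-557
hsa-miR-33a
hsa-miR-451
hsa-miR-483-5p
hsa-miR-486-5p
hsa-miR-194
hsa-miR-195*
hsa-miR-501-3p
hsa-miR-502-3p
hsa-miR-505*
hsa-miR-223
hsa-miR-564
hsa-miR-421
hsa-miR-339-3p
hsa-miR-598
hsa-miR-188-5p
hsa-miR-652
hsa-miR-19b-1*
hsa-miR-215
hsa-miR-219-5p
hsa-miR-873
hsa-miR-30c-1*
hsa-miR-328
hsa-miR-338-3p
hsa-miR-371-5p
hsa-miR-345
hsa-miR-378
hsa-miR-629
hsa-miR-629*
hsa-miR-663
hsa-miR-7-1*
hsa-miR-744
hsa-miR-877*
hsa-miR-9
hsa-miR-9*
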