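# Synthetic NMR-STAR v3 fragment for testing the chemical-shift reader.
# Values are artificial; they do not correspond to any deposited entry.
data_synthetic_shifts

save_assigned_chem_shift_list_1
   _Assigned_chem_shift_list.Sf_category   assigned_chemical_shifts
   _Assigned_chem_shift_list.ID            1

   loop_
      _Atom_chem_shift.ID
      _Atom_chem_shift.Seq_ID
      _Atom_chem_shift.Comp_ID
      _Atom_chem_shift.Atom_ID
      _Atom_chem_shift.Atom_type
      _Atom_chem_shift.Val
      _Atom_chem_shift.Val_err

      1   1   MET   CA   C   55.41   0.05
      2   1   MET   CB   C   32.85   0.05
      3   2   GLU   CA   C   56.72   0.05
      4   2   GLU   C    C   176.55  0.05
      5   3   LEU   CA   C   55.08   0.05
      6   3   LEU   HA   H   4.33    0.02
      7   3   LEU   N    N   121.8   0.1
      8   3   LEU   H    H   8.21    0.02
      9   4   LYS   CG   C   24.9    0.05
   stop_
save_
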