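# Assessment units spanning T219/T1170, T220/H1171 and T221/H1172: three
# solved structures of the RuvB hexamer with zero, one or two bound RuvA
# molecules. AU219 is the apo hexamer: three "super" interfaces per target
# (tight A:B/B:C, intermediate C:D/A:F, loose D:E/E:F), identical across the
# three targets, giving nine member interfaces grouped into three distinct
# interfaces. Per group, the best model over all member interfaces of all
# three targets represents the group. AU220 is the RuvB:RuvA binding mode,
# grouping interface 4 of T220 and T221.
au_configs:
  - au_id: AU219
    targets: [T219, T220, T221]
    description: RuvB apo-hexamer ring
    interface_groups:
      - id: "1"
        description: tight super interface (A:B and B:C)
        members:
          - {target: T219, interface: T219.1, chain_pairs: "A:B,B:C"}
          - {target: T220, interface: T220.1, chain_pairs: "A:B,B:C"}
          - {target: T221, interface: T221.1, chain_pairs: "A:B,B:C"}
      - id: "2"
        description: intermediate super interface (C:D and A:F)
        members:
          - {target: T219, interface: T219.2, chain_pairs: "C:D,A:F"}
          - {target: T220, interface: T220.2, chain_pairs: "C:D,A:F"}
          - {target: T221, interface: T221.2, chain_pairs: "C:D,A:F"}
      - id: "3"
        description: loose super interface (D:E and E:F)
        members:
          - {target: T219, interface: T219.3, chain_pairs: "D:E,E:F"}
          - {target: T220, interface: T220.3, chain_pairs: "D:E,E:F"}
          - {target: T221, interface: T221.3, chain_pairs: "D:E,E:F"}
  - au_id: AU220
    targets: [T220, T221]
    description: RuvB:RuvA binding mode
    interface_groups:
      - id: "4"
        description: RuvB/RuvA interface
        members:
          - {target: T220, interface: T220.4}
          - {target: T221, interface: T221.4}
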