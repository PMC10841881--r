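# Assessment units of T203/H1135 (SUN1 trimer-of-trimers bound to IRAG2).
# AU203.1 is the inner (minor) trimer with three interfaces; AU203.2 is the
# single unique inter-trimer interface of the outer (major) trimer.
au_configs:
  - au_id: AU203.1
    targets: [T203]
    description: minor SUN1 trimer plus bound IRAG2 peptide
    interface_groups:
      - id: T203.1
        members:
          - target: T203
            interface: T203.1
            description: SUN1-SUN1 internal trimer interface
      - id: T203.2
        members:
          - target: T203
            interface: T203.2
            description: primary IRAG2 peptide interface (850 A2)
      - id: T203.3
        members:
          - target: T203
            interface: T203.3
            description: secondary IRAG2 peptide interface (750 A2)
  - au_id: AU203.2
    targets: [T203]
    description: major (outer) trimer, single unique inter-trimer interface
    interface_groups:
      - id: T203.4
        members:
          - target: T203
            interface: T203.4
            description: inter-trimer interface (500 A2)
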