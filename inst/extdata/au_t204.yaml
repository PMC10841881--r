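# Assessment units of T204/H1137 (ABC transporter + MlaD hexamer with a
# helical tube). Structurally similar chain-pair interfaces are grouped into
# interfaces 1-8; the best result among a group's member interfaces stands
# for that interface. AU204.1 covers the tube (interface 1, grouped over the
# neighboring tube chain pairs) and the C-terminal "tube foot" domain
# (interface 2); AU204.2 covers the transmembrane assembly (interfaces 3-8).
au_configs:
  - au_id: AU204.1
    targets: [T204]
    description: alpha-helical tube and C-terminal domain
    interface_groups:
      - id: T204.1
        members:
          - target: T204
            interface: T204.1
            description: neighboring tube chain interfaces, grouped (~6000 A2 each)
      - id: T204.2
        members:
          - target: T204
            interface: T204.2
            description: C-terminal domain of non-neighboring tube chains (2750 A2)
  - au_id: AU204.2
    targets: [T204]
    description: transmembrane domain (ABC transporter + MlaD hexamer)
    interface_groups:
      - id: T204.3
        members:
          - target: T204
            interface: T204.3
            description: TM heterodimer (2250 A2)
      - id: T204.4
        members:
          - target: T204
            interface: T204.4
            description: TM/MlaD inter-domain interface (1500 A2)
      - id: T204.5
        members:
          - target: T204
            interface: T204.5
            description: TM/MlaD inter-domain interface (750 A2)
      - id: T204.6
        members:
          - target: T204
            interface: T204.6
            description: ABC homodimer (1500 A2)
      - id: T204.7
        members:
          - target: T204
            interface: T204.7
            description: TM/ABC interface (750 A2)
      - id: T204.8
        members:
          - target: T204
            interface: T204.8
            description: MlaD hexamer interface (1000 A2)
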