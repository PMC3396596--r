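>Seed|orange01 synthetic Orange seed
YVSEFQGLHREDFLQHV-RYLSYAEGTDPQNLVSPLHVYNAE
>Seed|orange02 synthetic Orange seed
YVSYQQGLHRE-FLQEV-RYLQTAEGVDPQGLVSHLHDGQAE
>Seed|orange03 synthetic Orange seed
YVSYLQG-HREDFLQHVS-YLSTAEGVDPQNLVSHLHNYQAW
>Seed|orange04 synthetic Orange seed
YVSYLQGLHREDFLQVPS-YLSTAEGVDHQNLVSHLHNYQAE
>Seed|orange05 synthetic Orange seed
YVSYLQGLHRE-FLQHS-RYLSTAEYVDPQNLVSHLHDYQHE
>Seed|orange06 synthetic Orange seed
YV-YLQGLHRE-FLQHV-RYLSTAEFVDPQNLVSHLHNYQAE
>Seed|orange07 synthetic Orange seed
YV-YLQG-HRE-FCQHVSRYLSTAEGVDPQNLVSHLHNYHAE
>Seed|orange08 synthetic Orange seed
QVSYLQGLHDE-FLQHV-RYLSTAEGWDPQNLVPYLHNPQHE
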