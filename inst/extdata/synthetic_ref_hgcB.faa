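>SYNREF01
VCPKYEQHVQRNAFAAQSLRKSHSMGPHKACMECGACKPHRINHCKDAGIRAVIQFTQPPCSMYVQQHGYALWWCAPMAHCQGKWTADHE
>SYNREF02
DCPKYSQHVQRNAFAAQSLRKSHSMGPHKACMECGACKPHRINHCKDAGIRAVIQFTQPPCSMYVQQHGYALWWCAPMKHCQGKWTADLE
>SYNREF03
VCPKYSQHVQRNAFAAQSLDKSHSMGPHKACMECGACKPHRINHCKDAGIRAVIQFTQPPCSMYVQQHGYAWWWCAPMAHCQGKWTADPE
>SYNREF04
VCPKYSQHVQRNAFAAQSLRTSHSMGPHKACMECGACKPHRINHCKDAGIRAVLQFTQPPCSMYVQQHGYALWWCAPMADCQGKWTADHE
>SYNREF05
VCPKYSQHVQYNAFANQSLRKSHSMGPHKACMECGACTPHRINHCKDAGIRAWYQYTQPPCSMYVQQTGYASWWCAPMAHCQYKWTADHE
>SYNREF06
VCPKYSQHVQYNAFANQSLRKSHSMGPHKACMECGACKPHRINHCKDAGIRAWYVFTQPPCSMYVQQTGYASWWCAPMAHCQYKWTADHE
>SYNREF07
VCPKYSQHFQYNTFANQSLRKSHSMGPHKACMECGACKPHRINHCLDAGIRAWYQFTQPPCSMYVQQTGYASWWCAPMAHCQYKWTSDHE
>SYNREF08
VCPKYSQHVQYNAFANQSLRKSHSMGPHKACMECGACLPHRINHCKDAGIRAWYQFTQPPCSMYVQQTGYASWWCAPMAHCQYKWTADHE
>SYNREF09
EQPKYSQHVQMNAFAAQNLRKVHSMRPDKACMECGACKARRRNHCIKDKIRAVYTTTQPEESMDFQQTGYAQWWCAPSAHCQYKWTTDRE
>SYNREF10
EQPKYSQHVQMNAFAAQNLRKVHSMRPRKACMECGACKARRRNHTIKDKIRAVYTTTQPEEKMDFQQTGYAQWWCAPSAHCQYKWTTDRE
>SYNREF11
EQPKYSQHVQMNAFEAQNLRKVHSMRPRKACMECGACKARRRNHCIKDKIRAVYTTTQPEESMDFQQTGYAQWWCAPSAHCQYKWTTDRE
>SYNREF12
EQPKYSQHVQMNAFAAQNLRKVHSMRPRKACMECGACKARRRNHCIKDKIRAVYTTTQPEESMDFQQTGYAQWWCAPSAHCRYKWTTDRE
>SYNREF13
VCPFCTQHVLRNAFVAISLRKSHSMLPRKACMECGACCAHYINHCYDAKIRAKYQFTQPTCSMPVQQTGVAQWWVAPMAHDQYKWTAVFQ
>SYNREF14
VCPFYTQNVQRNAFVAQSLRKSVSMLPRKACMECGACCAHYIHHCYDAKIRAKYQFTQPTCSMPVQQTGYAQWWVAPMAHDQYKWTAVFQ
>SYNREF15
VCPFYTQHVQRNAFVAQSLRKSHSMLPRKACMECGACCAHYINHCYDAKIRAKYQFTQPTCSMPVQQTGYAQWWVAPMAHDQYKWTAVFQ
>SYNREF16
VCPFYTQHVQRPAFVAQSLRKSHSMLPRAACMECGACCAHYINHCYDAKIRAKYQFTQPTCSMPVQQTGYAQWWVAPMAHDQYKWTAVFQ
>SYNREF17
VCPNYSQHVLRNAFAAQSLRKSNSMRPRSACMECGACKAHVSNHCKSAKIEAVYKFTYPECSMYVQWTGYAQWWCAPENPCQYTWTAGHE
>SYNREF18
VCPQYSQHVLRNAFTAQSLRKSNSMRPRSACMECGACKAHVINHCKSAKIRAVYKFTYPECSMYVQQTGYAQWWCAPENHCQYIWTAGHE
>SYNREF19
VCPQYSQHVLRTAFAAQSLRKSNSMRPRSACMECGACKAHVINRCKSAKIRSVYKFTYPECSMYVQQTGYAQWWCAPENHCQYIWEAGEE
>SYNREF20
VCPQYSQHVLRNAFAAQSLRKSNSMRPRSACMECGACKAHVINHCKSAKIRAVYKFTYPESSMYVQQTGYAQWWCAPENHCQYIWTAGHE
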