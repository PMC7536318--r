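>hgcB_ref01
VCPKYSQHVQRNAFAAQSLRKSHSMRPRKACMECGACKAHRINHMKDAKIRAVYQFTQFECSMYVQQTGYAQWWCAPMAHCQYKWFADHE
>hgcB_ref02
VCPKYSQHVGRNAFAAQNARKSHSMRPRYACMECGACKAHRINHCTDAKIRAVYQFTQPECSMYVQQTGYAQWWCAPNAHRQYKWTADHE
>hgcB_ref03
VCPYYSQHVQRNAFAAQSLQNSHSMRPRKACMECGACKAHRINWCKDAKIRAVYQFTQPECSMYVQQTGYAQWWCAPMAHCVYKWTADHE
>hgcB_ref04
VCPKYSQHVQRNAFAAQSLRKRHSMRPRKACMECGACKAHRINHCKDAKIRAVYQFTQPECSMYIQQTGYAQWWCAPMAHCQYKWTADHE
>hgcB_ref05
PCPKYSQHVQRNAFAAQSLRKSHSMRPRKACMECGACKAHRINHCKDDHIRAVYQFTQPECSMYVQQTGYAQWWCAPMAHCQYKWTADWE
>hgcB_ref06
VCPKYSCHVQRNAFAAQSLRKSHSMRPRKACMECGACKAHRINHCKDAKIRAVYQFTQPECSMYVQQTGYAQWWCAPMAHCQYKWTADHE
>hgcB_ref07
VCPKYSQHVQRNAFAAQSLRKSHSMRPRKACMECGACKAHRINHCKDAKIRAVYQFVQPECSMYVQQTGYAQWWCAPMAHCQYKWTADHE
>hgcB_ref08
VCPKYSQHVQRNAFAAQSLRKSHSMRPRKACMECGACKAHRINHCKDAKIRAVYQFHQPECSMYSQQTGYAQWWCAPMAHCQYKWTADHE
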