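>query
GVESCKFQAPEYQAHWWAMDFGCAVLQPYWPLEDVDMQMRCYPPDFDHSVPFFENTHHACYQEGHYSMHNYFWTWFYCPAGHFRQDWTRWSKVNMCIQQK
>t19
GVESCKFQAHEYQAHWWAMDFGVAVLQPYWPLEDVDMQMRCYPPDFDHSVPFFENTHHACYQEGHYSMHNYFWTWFYEPAGHFRQDSLRWSMVNMCIQQK
>t15
GVYSCLFQAREYQAHNVAMDFGNIVFVAYWPLEDVDMQMRCYPTDFDGSFPGFLNVTHICYWEGIKSWHNYFTTWFYSPAGHFNQDWTRDSKTNMCEQDK
>t14
AVYSCLFNARKYNANRVAMDFGNNVFQAYWPLEDVDMQDRCYPPDFDHSVPGFLNVHHICYWEGIYSWHNYFTTWFYSPAGHFNQDWTRDSKTNMCEQDK
>t17
AVYSCLFNAREYNANNVAMDFGNNVFQAYWPLEDVDMQDRCYPPDFDHSVPGFLNVHHICYWEGIYSWHIYFTTWFYSPAGHFNQDWTRDSKTNQCEQDK
>t12
GVESCKFQAREYQAHNVAMDFGNNMFQAYWPLEDVDDQMRLYPPDFDHSVPGFYNVSHICYWEGHYSMMNYFTTWFYSPAGHFNQDWTRDSFINMDIQKK
>t10
GVESCKFQAREYQAHNVAMDFGNNVFQAYWPLEDVDDQMRLYPPDFDHSVPGFYNVHHICYWEGHYSMMNYFTTWFYSPAGHFNQDWTRDSFTNMDIQDK
>t6
GVESCKFQADEYGAWDWAMDFGWNVLQPYWPLEDVDMQMRVYPPDFDHSVPHFENVHKACYWEGHYSMMNYFTTWFYSPAGHFNQDWTRDSKTNMAIQDK
>t2
GVPSCKFQMRMYQAHDWAMDFGLNVLQPYWTQEDVDMGMRVYPGVFDASVPFFENTVHACYWEGHYSMMNYFWVWFLSPAGHVNQDWTRWSKTIMLIQDK
>t13
GVESCKFQMRMTQAHFWPMDFGLNQLQPIWTQEDVDGQDRVYVGKFDASVPFFEITVHACYWEGHYSMMNYFWMWFLSIAGQFNQDWTRWSKTIMLIQDK
>t5
QVESDKFQMRMYQGHFWAMDFPLNVLQPIWTQEDHDGQARVYIGKFDASVPFFENTVNASYWEGHYSMMNYFWMWFLSPAWQFNQDLTRWSKTIMLIQDK
>t8
QVESCKFQMRMYQGHDWAMDFGLNVLQPIWTQEDVDGQMRVYIGKFDASVPFFENTVHACYWEGHYSMMNYFWMLFLSPAWQFNQHLTRAYKGIMLYQDK
>t11
SVESEKQQMRMYQAYHHHMDFGYNVLQPYKPQEDLDMQMRRMPGKFDASVPFFENTAHANYWEGHYSMMKYFWVGFLSPAGWFNQDWTRWSHTIMLIRDF
>t20
SVDREKQQMRMYQAYWHHMMFGYNVLQNYKPQEDLDMQMRMMPGKFDASVPFFENTAHANYWEGHYSMMNYFWVGFLSPSGWFNQDWTRWSHTIMVIQDF
>t3
GVESAKFQMVMYQDYGHHIDFGNNVLQPYKPQEDGDMQMRKMPGFFDASQPFFENTAHANYWEGHYSMMNEFWVGFLSPAGWFNQDWTRWSHTIMAIQHF
>t4
GVESAKFQMVMYQDYGHHIDFGNNVLQPYKPQEDGDMQMTKMPGKFDASSPFFENTAHASYWEGHYSMMNYFWVGDLQPAGWFNQDWTRWSHTIMAIQHF
>t7
GVESEKQQMRMYQAHDNAMDFGNRVLQPYKPQEFVDPQMPQNPGKFHASVPFFENTWHANYWEGHYPMMNYMWVWLLSPAGWFNQDWTRWSKTINQIQSF
>t9
GVESEKQQMRMYQAHDNAMDFGNRVLQPYKPQEFVDPQMRCNPIKFDASVPIFENTWHANYWEGHYPMMNYMWVWLLSPAQWFNQDWTRWSKTINCIQSF
>t16
GQESEKQQMRWYQAHDNGFQFGNRVLQPYKPSETVDPQMRCNPGKFDASVPFFENTAHANYWEGHYPMMNYMWVWVGSPAGWFNQDITRHSKTIMCIQSF
>t1
GVESEKQQMRMMQAHDNAQDFGNRVLQPYKPQEDGDPQMRCIPGKFDASVPFFENTAHANYWEGHDPMMNYMWVWVGSPAGWFRQDITRWSKTIMCIQSF
>t18
GVESWKFQMREYQAHDWAMDFGNNVLQPYWPQEDVDMQHRSYPGKFDHSVPFFENTHEAHYWEGHVSHMNYGWVWFYSPNGHFNQDWTRWSKTIMRIQDK
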